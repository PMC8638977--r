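#' The bundled gold-mines fixture
#'
#' Cleaner-production evaluations of three gold-mine centres (groups `G1`,
#' `G2`, `G3`, four observations each) recorded in fuzzy/interval-valued
#' form: each row carries a determinate part `a` and an indeterminacy
#' coefficient `b`. This is the worked-example dataset for the neutrosophic
#' JB test.
#'
#' @return A tibble with columns `group`, `a`, `b` (12 rows).
#' @examples
#' gold_mines()
#' @export
gold_mines <- function() {
  path <- system.file("extdata", "gold_mines.csv", package = "neutrojb",
                      mustWork = TRUE)
  read_neutro_data(path, layout = "ab", group_col = "group")
}

#' Read interval-valued data from a delimited text file
#'
#' Comma-separated, header row required, decimal point. Layout `"ab"` expects
#' numeric columns `a` and `b`; layout `"interval"` expects `lower` and
#' `upper` (converted to `a = lower`, `b = upper - lower`). An optional group
#' column is carried through.
#'
#' @param path Path to a CSV file.
#' @param layout `"ab"` or `"interval"`.
#' @param group_col Optional name of a group-label column.
#' @return A tibble in `ab` layout (`a`, `b`, plus the group column if
#'   requested), rows in file order.
#' @export
read_neutro_data <- function(path, layout = c("ab", "interval"),
                             group_col = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("Cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(data) == 0) stop("Empty file: ", path, call. = FALSE)
  if (!is.null(group_col) && !group_col %in% names(data)) {
    stop("Missing group column `", group_col, "` in ", path, call. = FALSE)
  }
  value_cols <- if (layout == "ab") c("a", "b") else c("lower", "upper")
  check_columns(data, value_cols)
  if (layout == "interval") {
    bad <- which(data$lower > data$upper)
    if (length(bad)) {
      stop("lower > upper at row(s) ", paste(bad, collapse = ", "), " of ",
           path, call. = FALSE)
    }
    data$a <- data$lower
    data$b <- data$upper - data$lower
  }
  keep <- c(if (!is.null(group_col)) group_col, "a", "b")
  tibble::as_tibble(data[keep])
}

#' Write interval-valued data to CSV
#'
#' Inverse of [read_neutro_data()] for the `ab` layout: values with at most
#' six decimal digits round-trip exactly.
#'
#' @param data A data frame with columns `a`, `b` and optionally a group
#'   column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_neutro_data <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}
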
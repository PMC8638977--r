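#' Construct a neutrosophic sample
#'
#' A neutrosophic sample is an ordered collection of observations
#' \eqn{z_k = a_k + b_k I}, each with a determinate part \eqn{a_k} and an
#' indeterminacy coefficient \eqn{b_k}, sharing one indeterminacy interval
#' \eqn{I \in [I_L, I_U]}. With all \eqn{b_k = 0} (or \eqn{I_L = I_U = 0}) the
#' sample is an ordinary numeric sample and every statistic in this package
#' collapses to its classical value.
#'
#' @param a Numeric vector of determinate parts (units of the measured
#'   variable).
#' @param b Numeric vector of indeterminacy coefficients, recycled from a
#'   scalar; same units as `a`. May be negative. Default 0 (classical data).
#' @param i Length-2 numeric: the indeterminacy interval `c(i_lower, i_upper)`
#'   with `0 <= i_lower <= i_upper`. Default `c(0, 1)`.
#'
#' @return An object of class `neutro_sample`: a list with elements `a`, `b`,
#'   `i_lower`, `i_upper`.
#' @examples
#' s <- neutro_sample(a = c(0.32, 0.09, 0.22, 0.13),
#'                    b = c(0.43, 0.15, 0.31, 0.44))
#' realize(s, 0)   # the determinate series
#' realize(s, 1)   # the series at full indeterminacy
#' @export
neutro_sample <- function(a, b = 0, i = c(0, 1)) {
  if (!is.numeric(a) || length(a) == 0) {
    stop("`a` must be a nonempty numeric vector.", call. = FALSE)
  }
  if (!is.numeric(b)) stop("`b` must be numeric.", call. = FALSE)
  if (length(b) == 1L) b <- rep(b, length(a))
  if (length(b) != length(a)) {
    stop("`b` must have length 1 or length(a).", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("All determinate parts `a` and coefficients `b` must be finite.",
         call. = FALSE)
  }
  i <- validate_indeterminacy(i)
  structure(
    list(a = as.numeric(a), b = as.numeric(b),
         i_lower = i[[1]], i_upper = i[[2]]),
    class = "neutro_sample"
  )
}

validate_indeterminacy <- function(i) {
  if (!is.numeric(i) || length(i) != 2L || !all(is.finite(i))) {
    stop("`i` must be a finite numeric vector c(i_lower, i_upper).",
         call. = FALSE)
  }
  if (i[[1]] < 0 || i[[1]] > i[[2]]) {
    stop("Indeterminacy interval requires 0 <= i_lower <= i_upper; got [",
         i[[1]], ", ", i[[2]], "].", call. = FALSE)
  }
  as.numeric(i)
}

#' Coerce a data frame to a neutrosophic sample
#'
#' Two layouts are supported. `"ab"` expects columns holding the determinate
#' part and the indeterminacy coefficient directly. `"interval"` expects
#' lower/upper bound columns `[L, U]`; these convert via `a = L`,
#' `b = U - L`, with the indeterminacy interval fixed at `[0, 1]` so that the
#' realized series sweeps the recorded interval.
#'
#' @param data A data frame.
#' @param layout `"ab"` or `"interval"`.
#' @param a,b Column names for the `"ab"` layout. Defaults `"a"`, `"b"`.
#' @param lower,upper Column names for the `"interval"` layout. Defaults
#'   `"lower"`, `"upper"`.
#' @param i Indeterminacy interval for the `"ab"` layout (ignored, forced to
#'   `c(0, 1)`, for `"interval"`).
#' @return A [neutro_sample()].
#' @export
as_neutro_sample <- function(data, layout = c("ab", "interval"),
                             a = "a", b = "b",
                             lower = "lower", upper = "upper",
                             i = c(0, 1)) {
  layout <- match.arg(layout)
  data <- as.data.frame(data)
  if (layout == "ab") {
    check_columns(data, c(a, b))
    neutro_sample(data[[a]], data[[b]], i = i)
  } else {
    check_columns(data, c(lower, upper))
    lo <- data[[lower]]
    up <- data[[upper]]
    bad <- which(lo > up)
    if (length(bad)) {
      stop("Interval layout requires lower <= upper; violated at row(s) ",
           paste(bad, collapse = ", "), ".", call. = FALSE)
    }
    neutro_sample(lo, up - lo, i = c(0, 1))
  }
}

check_columns <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("Missing column(s): ", paste(missing, collapse = ", "), ".",
         call. = FALSE)
  }
  for (col in cols) {
    x <- data[[col]]
    if (!is.numeric(x)) {
      as_num <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(as_num) & !is.na(x))
      stop("Column `", col, "` must be numeric; non-numeric cell(s) at row(s) ",
           paste(if (length(bad)) bad else "?", collapse = ", "), ".",
           call. = FALSE)
    }
    bad <- which(!is.finite(x))
    if (length(bad)) {
      stop("Non-finite value in column `", col, "` at row(s) ",
           paste(bad, collapse = ", "), ".", call. = FALSE)
    }
  }
  invisible(data)
}

#' Realize a neutrosophic sample at a fixed indeterminacy level
#'
#' Evaluates \eqn{z_k = a_k + b_k i} for every observation, preserving order.
#' `realize(s, 0)` returns the determinate parts unchanged.
#'
#' @param sample A [neutro_sample()].
#' @param i A single finite indeterminacy level.
#' @return Numeric vector of realized values.
#' @export
realize <- function(sample, i) {
  stopifnot(inherits(sample, "neutro_sample"))
  if (!is.numeric(i) || length(i) != 1L || !is.finite(i)) {
    stop("`i` must be a single finite number.", call. = FALSE)
  }
  sample$a + sample$b * i
}

#' @export
print.neutro_sample <- function(x, ...) {
  n <- length(x$a)
  cat(sprintf("<neutro_sample> n = %d, I in [%g, %g]\n", n, x$i_lower, x$i_upper))
  show <- utils::head(tibble::tibble(a = x$a, b = x$b), 10)
  print(show)
  if (n > 10) cat("# ... with", n - 10, "more observations\n")
  invisible(x)
}

#' @export
length.neutro_sample <- function(x) length(x$a)

#' @method as_tibble neutro_sample
#' @export
as_tibble.neutro_sample <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b)
}
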
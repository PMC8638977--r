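# Classical moment helpers, divisor-n convention throughout.
# S = sqrt(sum(dev^2)/n); skew = sum(dev^3)/(n S^3); excess kurt = sum(dev^4)/(n S^4) - 3.

moment_dev <- function(x) x - mean(x)

sd_n <- function(x) sqrt(sum(moment_dev(x)^2) / length(x))

skewness_n <- function(x) {
  d <- moment_dev(x)
  s <- sd_n(x)
  if (s == 0) degenerate_error()
  sum(d^3) / (length(x) * s^3)
}

ekurtosis_n <- function(x) {
  d <- moment_dev(x)
  s <- sd_n(x)
  if (s == 0) degenerate_error()
  sum(d^4) / (length(x) * s^4) - 3
}

degenerate_error <- function(endpoint = NULL) {
  msg <- "Degenerate sample: all realized values equal (zero standard deviation)"
  if (!is.null(endpoint)) msg <- paste0(msg, " at the ", endpoint, " endpoint")
  stop(errorCondition(paste0(msg, "."),
                      class = c("neutrojb_degenerate_error", "neutrojb_error")))
}

at_endpoints <- function(sample, f) {
  eval_at <- function(i, endpoint) {
    tryCatch(f(realize(sample, i)),
             neutrojb_degenerate_error = function(e) degenerate_error(endpoint))
  }
  neutro_interval(eval_at(sample$i_lower, "lower"),
                  eval_at(sample$i_upper, "upper"))
}

#' Neutrosophic mean
#'
#' The mean of a neutrosophic sample is itself a neutrosophic number
#' \eqn{\bar z = \bar a + \bar b I}: the pair of the mean determinate part and
#' the mean indeterminacy coefficient. The realized mean at any level `i`
#' equals `a_bar + b_bar * i`.
#'
#' @param sample A [neutro_sample()].
#' @return A named list with `a_bar` and `b_bar`.
#' @examples
#' neutro_mean(neutro_sample(c(0.32, 0.09, 0.22, 0.13),
#'                           c(0.43, 0.15, 0.31, 0.44)))
#' @export
neutro_mean <- function(sample) {
  stopifnot(inherits(sample, "neutro_sample"))
  list(a_bar = mean(sample$a), b_bar = mean(sample$b))
}

#' Per-observation neutrosophic deviations
#'
#' The deviation of each observation from the neutrosophic mean,
#' \eqn{(a_k - \bar a) + (b_k - \bar b) I}, evaluated at both endpoints of the
#' indeterminacy interval. Deviations sum to zero at each endpoint.
#'
#' @inheritParams neutro_mean
#' @return A tibble with one row per observation: `obs`, `at_lower`,
#'   `at_upper`.
#' @export
neutro_deviations <- function(sample) {
  stopifnot(inherits(sample, "neutro_sample"))
  m <- neutro_mean(sample)
  dev_at <- function(i) (sample$a - m$a_bar) + (sample$b - m$b_bar) * i
  tibble::tibble(
    obs = seq_along(sample$a),
    at_lower = dev_at(sample$i_lower),
    at_upper = dev_at(sample$i_upper)
  )
}

#' Neutrosophic sum of squares
#'
#' Sum of squared deviations of the realized series at each endpoint of the
#' indeterminacy interval. Nonnegative at both endpoints; both endpoints are
#' zero for a constant sample.
#'
#' @inheritParams neutro_mean
#' @return A [neutro_interval()].
#' @export
neutro_ss <- function(sample) {
  stopifnot(inherits(sample, "neutro_sample"))
  at_endpoints(sample, function(z) sum(moment_dev(z)^2))
}

#' Neutrosophic standard deviation
#'
#' `sqrt(SS / n)` at each endpoint (population divisor `n`, not `n - 1`).
#'
#' @inheritParams neutro_mean
#' @return A [neutro_interval()].
#' @export
neutro_std <- function(sample) {
  stopifnot(inherits(sample, "neutro_sample"))
  at_endpoints(sample, sd_n)
}

#' Neutrosophic skewness
#'
#' The third standardized moment \eqn{\sum d^3 / (n S^3)} of the realized
#' series at each endpoint of the indeterminacy interval.
#'
#' @inheritParams neutro_mean
#' @return A [neutro_interval()]. Errors (class
#'   `neutrojb_degenerate_error`) if the realized series is constant at an
#'   endpoint.
#' @export
neutro_skewness <- function(sample) {
  stopifnot(inherits(sample, "neutro_sample"))
  check_moment_n(sample)
  at_endpoints(sample, skewness_n)
}

#' Neutrosophic excess kurtosis
#'
#' The fourth standardized moment minus 3, \eqn{\sum d^4 / (n S^4) - 3}, of
#' the realized series at each endpoint. Zero for normal moments; bounded
#' below by \eqn{-2} for any real series.
#'
#' @inheritParams neutro_mean
#' @return A [neutro_interval()]. Errors on a constant realized series.
#' @export
neutro_excess_kurtosis <- function(sample) {
  stopifnot(inherits(sample, "neutro_sample"))
  check_moment_n(sample)
  at_endpoints(sample, ekurtosis_n)
}

check_moment_n <- function(sample) {
  if (length(sample$a) < 3L) {
    stop("Skewness/kurtosis require n >= 3.", call. = FALSE)
  }
  invisible(sample)
}

#' Interval-valued descriptive moments, one row per group
#'
#' Data-frame front end for the neutrosophic descriptive statistics: for each
#' group it reports the mean pair \eqn{(\bar a, \bar b)} and the sum of
#' squares, standard deviation, skewness and excess kurtosis intervals,
#' each evaluated at the two endpoints of the indeterminacy interval.
#'
#' @param data A data frame with one row per observation.
#' @param a,b Column names of the determinate part and indeterminacy
#'   coefficient (`"ab"` layout), or
#' @param lower,upper column names of interval bounds (`"interval"` layout).
#' @param group Optional column name labelling groups; `NULL` treats the whole
#'   frame as one group.
#' @param i Indeterminacy interval `c(i_lower, i_upper)`.
#' @param layout `"ab"` (default) or `"interval"`.
#' @return A tibble with columns `group`, `n`, `a_bar`, `b_bar`,
#'   `ss_lower`, `ss_upper`, `sd_lower`, `sd_upper`, `skew_lower`,
#'   `skew_upper`, `ekurt_lower`, `ekurt_upper`.
#' @examples
#' gold_mines() |> neutro_describe(group = "group")
#' @export
neutro_describe <- function(data, a = "a", b = "b", group = NULL,
                            i = c(0, 1), layout = c("ab", "interval"),
                            lower = "lower", upper = "upper") {
  layout <- match.arg(layout)
  samples <- split_samples(data, layout, a, b, lower, upper, group, i)
  purrr::map_dfr(names(samples), function(g) {
    s <- samples[[g]]
    m <- neutro_mean(s)
    ss <- neutro_ss(s)
    sd <- neutro_std(s)
    sk <- neutro_skewness(s)
    ku <- neutro_excess_kurtosis(s)
    tibble::tibble(
      group = g, n = length(s),
      a_bar = m$a_bar, b_bar = m$b_bar,
      ss_lower = ss$at_lower, ss_upper = ss$at_upper,
      sd_lower = sd$at_lower, sd_upper = sd$at_upper,
      skew_lower = sk$at_lower, skew_upper = sk$at_upper,
      ekurt_lower = ku$at_lower, ekurt_upper = ku$at_upper
    )
  })
}

# Split a data frame into one neutro_sample per group, preserving file order.
split_samples <- function(data, layout, a, b, lower, upper, group, i) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) stop("`data` has no rows.", call. = FALSE)
  if (is.null(group)) {
    groups <- list(sample = data)
  } else {
    if (!group %in% names(data)) {
      stop("Missing group column `", group, "`.", call. = FALSE)
    }
    labels <- as.character(data[[group]])
    groups <- split(data, factor(labels, levels = unique(labels)))
  }
  lapply(groups, as_neutro_sample, layout = layout, a = a, b = b,
         lower = lower, upper = upper, i = i)
}
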
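#' Classical Jarque-Bera statistic
#'
#' \eqn{JB = n (S^2/6 + K^2/24)} where `S` is the divisor-`n` sample skewness
#' and `K` the divisor-`n` excess kurtosis. Zero when the sample moments match
#' the normal distribution's (skewness 0, excess kurtosis 0); invariant under
#' affine transformations of the series.
#'
#' @param series Numeric vector, `n >= 3`, non-constant.
#' @return The JB statistic (nonnegative scalar).
#' @examples
#' classical_jb(c(0.32, 0.09, 0.22, 0.13))
#' @export
classical_jb <- function(series) {
  if (!is.numeric(series) || length(series) < 3L) {
    stop("`series` must be numeric with n >= 3.", call. = FALSE)
  }
  if (!all(is.finite(series))) stop("`series` must be finite.", call. = FALSE)
  n <- length(series)
  s <- skewness_n(series)
  k <- ekurtosis_n(series)
  n * (s^2 / 6 + k^2 / 24)
}

#' Jarque-Bera p-value
#'
#' Upper tail of the chi-square distribution with two degrees of freedom, the
#' asymptotic null law of the JB statistic. Strictly decreasing in `jb`;
#' equals `exp(-jb/2)` in closed form.
#'
#' @param jb Nonnegative JB statistic (vectorised).
#' @return Upper-tail probability in (0, 1].
#' @export
jb_p_value <- function(jb) {
  if (!is.numeric(jb) || any(!is.finite(jb)) || any(jb < 0)) {
    stop("`jb` must be finite and nonnegative.", call. = FALSE)
  }
  stats::pchisq(jb, df = 2, lower.tail = FALSE)
}

#' Neutrosophic Jarque-Bera statistic
#'
#' \eqn{JB_N = n (k_3^2/6 + k_4^2/24)} computed from the neutrosophic
#' skewness \eqn{k_3} and excess kurtosis \eqn{k_4} at each endpoint of the
#' indeterminacy interval. Equals [classical_jb()] of the realized series at
#' each endpoint; with all `b = 0` both endpoints reduce to the classical JB
#' of the determinate series.
#'
#' @param sample A [neutro_sample()].
#' @return A [neutro_interval()] holding `(JB_L, JB_U)`.
#' @examples
#' s <- neutro_sample(c(0.32, 0.09, 0.22, 0.13), c(0.43, 0.15, 0.31, 0.44))
#' neutro_jb(s)
#' @export
neutro_jb <- function(sample) {
  stopifnot(inherits(sample, "neutro_sample"))
  check_moment_n(sample)
  n <- length(sample$a)
  sk <- neutro_skewness(sample)
  ku <- neutro_excess_kurtosis(sample)
  jb_at <- function(s, k) n * (s^2 / 6 + k^2 / 24)
  neutro_interval(jb_at(sk$at_lower, ku$at_lower),
                  jb_at(sk$at_upper, ku$at_upper))
}

#' Measure of indeterminacy of a JB interval
#'
#' The relative width `(max - min) / max` of the (sorted) JB interval: the
#' fraction of the statistic's largest attainable value that is attributable
#' to the data's indeterminacy. Zero for a degenerate interval, and always in
#' `[0, 1)`.
#'
#' @param jb A [neutro_interval()] or a length-2 numeric `(JB_L, JB_U)`.
#' @return A scalar in `[0, 1)`.
#' @examples
#' indeterminacy_measure(c(0.4047, 1.1099))
#' @export
indeterminacy_measure <- function(jb) {
  jb <- as_jb_interval(jb)
  if (jb$min < 0) stop("JB endpoints must be nonnegative.", call. = FALSE)
  if (jb$max == 0) return(0)
  (jb$max - jb$min) / jb$max
}

#' Neutrosophic form of a JB interval
#'
#' Renders the statistic as determinate plus indeterminate part,
#' `JB_N = JB_L + JB_U I_N; I_N in [0, m]`, with `m` the
#' [indeterminacy_measure()]. Substituting `I_N = m` recovers `JB_U`
#' (up to rounding).
#'
#' @inheritParams indeterminacy_measure
#' @param digits Decimal places used in the rendering.
#' @return A character string.
#' @examples
#' neutrosophic_form(c(0.4047, 1.1099))
#' @export
neutrosophic_form <- function(jb, digits = 4) {
  jb <- as_jb_interval(jb)
  m <- indeterminacy_measure(jb)
  sprintf("JB_N = %s + %s I_N; I_N in [0, %s]",
          format(round(jb$min, digits)), format(round(jb$max, digits)),
          format(round(m, digits)))
}

as_jb_interval <- function(jb) {
  if (inherits(jb, "neutro_interval")) return(jb)
  if (is.numeric(jb) && length(jb) == 2L && all(is.finite(jb))) {
    return(neutro_interval(jb[[1]], jb[[2]]))
  }
  stop("`jb` must be a neutro_interval or a length-2 numeric.", call. = FALSE)
}

#' Tri-state decision for the neutrosophic JB test
#'
#' Compares the JB interval with the critical value: *accept* normality when
#' both endpoints fall below it, *reject* when both fall at or above it, and
#' *indeterminate* when the interval straddles it — the genuinely uncertain
#' outcome introduced by the data's indeterminacy. The default critical value
#' is the upper-\eqn{\alpha} quantile of the chi-square distribution with two
#' degrees of freedom (\eqn{-2\log\alpha}); a user-supplied value overrides
#' it (e.g. 7.815, the 3-df quantile sometimes used in applied work).
#'
#' @inheritParams indeterminacy_measure
#' @param alpha Significance level in (0, 1).
#' @param critical_value Optional positive critical value overriding the
#'   chi-square(2) default.
#' @return A `jb_result` list: `jb`, `p_value` (both [neutro_interval()]s),
#'   `alpha`, `critical_value`, `decision` (`"accept"`, `"reject"` or
#'   `"indeterminate"`), `indeterminacy_measure`, `neutrosophic_form`.
#' @examples
#' jb_decision(c(0.4047, 1.1099), alpha = 0.05, critical_value = 7.815)
#' @export
jb_decision <- function(jb, alpha = 0.05, critical_value = NULL) {
  jb <- as_jb_interval(jb)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1).", call. = FALSE)
  }
  if (jb$min < 0) stop("JB endpoints must be nonnegative.", call. = FALSE)
  if (is.null(critical_value)) {
    critical_value <- stats::qchisq(alpha, df = 2, lower.tail = FALSE)
  } else if (!is.numeric(critical_value) || length(critical_value) != 1L ||
             !is.finite(critical_value) || critical_value <= 0) {
    stop("`critical_value` must be a single positive number.", call. = FALSE)
  }
  decision <- if (jb$max < critical_value) {
    "accept"
  } else if (jb$min >= critical_value) {
    "reject"
  } else {
    "indeterminate"
  }
  structure(
    list(
      jb = jb,
      p_value = neutro_interval(jb_p_value(jb$at_lower),
                                jb_p_value(jb$at_upper)),
      alpha = alpha,
      critical_value = critical_value,
      decision = decision,
      indeterminacy_measure = indeterminacy_measure(jb),
      neutrosophic_form = neutrosophic_form(jb)
    ),
    class = "jb_result"
  )
}

#' @export
print.jb_result <- function(x, digits = 4, ...) {
  cat("Neutrosophic Jarque-Bera decision\n")
  cat(sprintf("  JB_N: [%s, %s]   p: [%s, %s]\n",
              format(round(x$jb$at_lower, digits)),
              format(round(x$jb$at_upper, digits)),
              format(round(x$p_value$min, digits)),
              format(round(x$p_value$max, digits))))
  cat(sprintf("  alpha = %g, critical value = %s\n",
              x$alpha, format(round(x$critical_value, digits))))
  cat(sprintf("  decision: %s   indeterminacy: %s\n",
              x$decision, format(round(x$indeterminacy_measure, digits))))
  cat("  ", x$neutrosophic_form, "\n", sep = "")
  invisible(x)
}
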
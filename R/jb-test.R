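#' Neutrosophic Jarque-Bera normality test on a data frame
#'
#' The main entry point. For each group it runs the full procedure: means of
#' the determinate and indeterminate parts, deviations, sum of squares,
#' skewness and excess kurtosis at both endpoints of the indeterminacy
#' interval, the JB interval \eqn{[JB_L, JB_U]}, endpoint-wise p-values, the
#' tri-state accept/indeterminate/reject decision against the critical value,
#' the measure of indeterminacy, and the neutrosophic form
#' `JB_N = JB_L + JB_U I_N`.
#'
#' A group whose realized series is constant at an endpoint yields a row of
#' `NA` statistics with the error message in `note`; other groups are still
#' processed.
#'
#' @inheritParams neutro_describe
#' @param alpha Significance level in (0, 1).
#' @param critical_value Optional override of the chi-square(2 df) critical
#'   value \eqn{-2\log\alpha}.
#' @return An object of class `neutro_jb_test`: a list with `results` (a
#'   tibble, one row per group), `alpha`, `critical_value`,
#'   `critical_value_default` (logical), and `i`. Use [generics::tidy()] for
#'   the per-group tibble, [generics::glance()] for a one-row summary, and
#'   [ggplot2::autoplot()] for an interval plot.
#' @examples
#' fit <- gold_mines() |> neutro_jb_test(group = "group", critical_value = 7.815)
#' fit
#' tidy(fit)
#' glance(fit)
#' @export
neutro_jb_test <- function(data, a = "a", b = "b", group = NULL,
                           i = c(0, 1), alpha = 0.05, critical_value = NULL,
                           layout = c("ab", "interval"),
                           lower = "lower", upper = "upper") {
  layout <- match.arg(layout)
  i <- validate_indeterminacy(i)
  samples <- split_samples(data, layout, a, b, lower, upper, group, i)
  default_cv <- is.null(critical_value)
  cv <- if (default_cv) stats::qchisq(alpha, df = 2, lower.tail = FALSE)
        else critical_value

  results <- purrr::map_dfr(names(samples), function(g) {
    s <- samples[[g]]
    out <- tryCatch(group_result(s, alpha, cv), neutrojb_error = identity,
                    error = identity)
    if (inherits(out, "condition")) {
      return(tibble::tibble(
        group = g, n = length(s), a_bar = mean(s$a), b_bar = mean(s$b),
        ss_lower = NA_real_, ss_upper = NA_real_,
        skew_lower = NA_real_, skew_upper = NA_real_,
        ekurt_lower = NA_real_, ekurt_upper = NA_real_,
        jb_lower = NA_real_, jb_upper = NA_real_,
        p_lower = NA_real_, p_upper = NA_real_,
        decision = NA_character_, indeterminacy = NA_real_,
        neutrosophic_form = NA_character_, note = conditionMessage(out)
      ))
    }
    out$group <- g
    dplyr::relocate(out, "group")
  })

  structure(
    list(results = results, alpha = alpha, critical_value = cv,
         critical_value_default = default_cv, i = i),
    class = "neutro_jb_test"
  )
}

group_result <- function(s, alpha, cv) {
  m <- neutro_mean(s)
  ss <- neutro_ss(s)
  sk <- neutro_skewness(s)
  ku <- neutro_excess_kurtosis(s)
  jb <- neutro_jb(s)
  dec <- jb_decision(jb, alpha = alpha, critical_value = cv)
  tibble::tibble(
    n = length(s), a_bar = m$a_bar, b_bar = m$b_bar,
    ss_lower = ss$at_lower, ss_upper = ss$at_upper,
    skew_lower = sk$at_lower, skew_upper = sk$at_upper,
    ekurt_lower = ku$at_lower, ekurt_upper = ku$at_upper,
    jb_lower = jb$at_lower, jb_upper = jb$at_upper,
    p_lower = dec$p_value$at_lower, p_upper = dec$p_value$at_upper,
    decision = dec$decision, indeterminacy = dec$indeterminacy_measure,
    neutrosophic_form = dec$neutrosophic_form, note = NA_character_
  )
}

#' @export
print.neutro_jb_test <- function(x, digits = 4, ...) {
  cat("Neutrosophic Jarque-Bera normality test\n")
  cat(sprintf("  indeterminacy interval I in [%g, %g]; alpha = %g; critical value = %s%s\n",
              x$i[[1]], x$i[[2]], x$alpha,
              format(round(x$critical_value, digits)),
              if (x$critical_value_default) " (chi-square, 2 df)" else " (user-supplied)"))
  shown <- dplyr::mutate(
    x$results,
    dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits))
  )
  print(dplyr::select(shown, -"neutrosophic_form", -"note"), n = Inf)
  forms <- x$results$neutrosophic_form
  ok <- !is.na(forms)
  if (any(ok)) {
    cat("Neutrosophic forms:\n")
    for (k in which(ok)) cat("  ", x$results$group[[k]], ": ", forms[[k]], "\n", sep = "")
  }
  bad <- which(!is.na(x$results$note))
  for (k in bad) {
    cat("Group ", x$results$group[[k]], ": ", x$results$note[[k]], "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-group results of a neutrosophic JB test
#'
#' @param x A [neutro_jb_test()] object.
#' @param ... Unused.
#' @return The per-group results tibble.
#' @method tidy neutro_jb_test
#' @export
tidy.neutro_jb_test <- function(x, ...) x$results

#' One-row summary of a neutrosophic JB test
#'
#' @param x A [neutro_jb_test()] object.
#' @param ... Unused.
#' @return A one-row tibble: group counts by decision, `alpha`,
#'   `critical_value`, indeterminacy interval.
#' @method glance neutro_jb_test
#' @export
glance.neutro_jb_test <- function(x, ...) {
  d <- x$results$decision
  tibble::tibble(
    n_groups = nrow(x$results),
    n_accept = sum(d == "accept", na.rm = TRUE),
    n_reject = sum(d == "reject", na.rm = TRUE),
    n_indeterminate = sum(d == "indeterminate", na.rm = TRUE),
    n_failed = sum(is.na(d)),
    alpha = x$alpha,
    critical_value = x$critical_value,
    i_lower = x$i[[1]],
    i_upper = x$i[[2]]
  )
}

#' Plot the JB intervals of a neutrosophic JB test
#'
#' One horizontal segment per group spanning the sorted JB interval, points at
#' the endpoint-evaluated values, and a dashed line at the critical value.
#' Groups are coloured by decision.
#'
#' @param object A [neutro_jb_test()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neutro_jb_test
#' @export
autoplot.neutro_jb_test <- function(object, ...) {
  res <- dplyr::filter(object$results, !is.na(.data$jb_lower))
  long <- tidyr::pivot_longer(res, c("jb_lower", "jb_upper"),
                              names_to = "endpoint", values_to = "jb")
  ggplot2::ggplot(res, ggplot2::aes(y = .data$group)) +
    ggplot2::geom_segment(ggplot2::aes(
      x = pmin(.data$jb_lower, .data$jb_upper),
      xend = pmax(.data$jb_lower, .data$jb_upper),
      yend = .data$group, colour = .data$decision), linewidth = 1.2) +
    ggplot2::geom_point(data = long,
                        ggplot2::aes(x = .data$jb, colour = .data$decision),
                        size = 2.5) +
    ggplot2::geom_vline(xintercept = object$critical_value,
                        linetype = "dashed") +
    ggplot2::labs(x = "JB_N", y = NULL, colour = "decision",
                  title = "Neutrosophic Jarque-Bera intervals",
                  subtitle = sprintf("dashed line: critical value %.3f",
                                     object$critical_value)) +
    ggplot2::theme_minimal()
}
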
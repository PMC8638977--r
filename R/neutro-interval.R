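#' Interval-valued statistic
#'
#' Every neutrosophic statistic in this package is reported as the ordered
#' pair of its classical value on the realized series at `I_L` and at `I_U`
#' (endpoint evaluation). The pair is kept in endpoint correspondence —
#' `at_lower` may exceed `at_upper` — and a sorted `[min, max]` view is
#' attached for interval comparisons.
#'
#' @param at_lower Statistic evaluated at the lower indeterminacy endpoint.
#' @param at_upper Statistic evaluated at the upper endpoint.
#' @return A `neutro_interval` object.
#' @export
neutro_interval <- function(at_lower, at_upper) {
  stopifnot(is.numeric(at_lower), is.numeric(at_upper),
            length(at_lower) == 1L, length(at_upper) == 1L)
  structure(
    list(at_lower = as.numeric(at_lower), at_upper = as.numeric(at_upper),
         min = min(at_lower, at_upper), max = max(at_lower, at_upper)),
    class = "neutro_interval"
  )
}

#' @export
print.neutro_interval <- function(x, digits = 4, ...) {
  cat(sprintf("<neutro_interval> (%s, %s)  sorted [%s, %s]\n",
              format(round(x$at_lower, digits)),
              format(round(x$at_upper, digits)),
              format(round(x$min, digits)),
              format(round(x$max, digits))))
  invisible(x)
}

#' @method as_tibble neutro_interval
#' @export
as_tibble.neutro_interval <- function(x, ...) {
  tibble::tibble(at_lower = x$at_lower, at_upper = x$at_upper,
                 min = x$min, max = x$max)
}

is_degenerate_interval <- function(x, tol = 0) {
  abs(x$at_upper - x$at_lower) <= tol
}
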
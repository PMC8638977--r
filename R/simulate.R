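#' Define a Monte-Carlo scenario
#'
#' A scenario fixes everything needed to replicate a size/power experiment:
#' the sampling distribution of the determinate part, the model for the
#' indeterminacy coefficients, the indeterminacy interval, the sample size,
#' the number of replicates, the significance level and the root seed.
#'
#' Determinate-part distributions: `"normal"` (`mean`, `sd`), `"uniform"`
#' (`min`, `max`), `"exponential"` (`rate`), `"t"` (`df`), `"chisq"` (`df`).
#' Indeterminacy-coefficient models: `"zero"` (classical data),
#' `"constant"` (`b = b_scale`), `"proportional"` (`b = b_scale * |a|`),
#' `"halfnormal"` (`b = |N(0, b_scale)|`).
#'
#' @param n Sample size per replicate, `>= 3`.
#' @param dist Distribution label for the determinate part.
#' @param dist_args Named list of distribution parameters (see above).
#' @param b_model Indeterminacy-coefficient model label.
#' @param b_scale Nonnegative scale of the `b` model (ignored for `"zero"`).
#' @param i Indeterminacy interval `c(i_lower, i_upper)`.
#' @param replicates Number of Monte-Carlo replicates, `>= 1`.
#' @param alpha Significance level.
#' @param seed Integer root seed; every quantity derived from the scenario is
#'   deterministic given it.
#' @param critical_value Optional critical-value override passed to
#'   [jb_decision()].
#' @param max_draws Cap on `replicates * n`, a guard against accidental
#'   huge runs.
#' @return A `scenario_spec` list.
#' @examples
#' sim_scenario(n = 50, dist = "normal", replicates = 200, seed = 1)
#' @export
sim_scenario <- function(n, dist = c("normal", "uniform", "exponential", "t", "chisq"),
                         dist_args = list(), b_model = c("zero", "constant",
                                                         "proportional", "halfnormal"),
                         b_scale = 0, i = c(0, 1), replicates = 1000,
                         alpha = 0.05, seed = 1, critical_value = NULL,
                         max_draws = 5e7) {
  if (is.character(dist) && length(dist) == 1 &&
      !dist %in% c("normal", "uniform", "exponential", "t", "chisq")) {
    stop("Unknown distribution label `", dist, "`.", call. = FALSE)
  }
  dist <- match.arg(dist)
  if (is.character(b_model) && length(b_model) == 1 &&
      !b_model %in% c("zero", "constant", "proportional", "halfnormal")) {
    stop("Unknown b_model label `", b_model, "`.", call. = FALSE)
  }
  b_model <- match.arg(b_model)
  stopifnot(is.numeric(n), length(n) == 1, is.finite(n), n >= 3,
            is.numeric(replicates), length(replicates) == 1, replicates >= 1,
            is.numeric(b_scale), length(b_scale) == 1, is.finite(b_scale),
            b_scale >= 0,
            is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (replicates * n > max_draws) {
    stop("replicates * n exceeds max_draws (", max_draws, ").", call. = FALSE)
  }
  i <- validate_indeterminacy(i)
  structure(
    list(n = as.integer(n), dist = dist, dist_args = dist_args,
         b_model = b_model, b_scale = b_scale, i = i,
         replicates = as.integer(replicates), alpha = alpha,
         seed = as.integer(seed), critical_value = critical_value),
    class = "scenario_spec"
  )
}

draw_determinate <- function(spec) {
  args <- spec$dist_args
  switch(spec$dist,
    normal = stats::rnorm(spec$n, mean = args$mean %||% 0, sd = args$sd %||% 1),
    uniform = stats::runif(spec$n, min = args$min %||% 0, max = args$max %||% 1),
    exponential = stats::rexp(spec$n, rate = args$rate %||% 1),
    t = stats::rt(spec$n, df = args$df %||% 5),
    chisq = stats::rchisq(spec$n, df = args$df %||% 2)
  )
}

draw_b <- function(spec, a) {
  switch(spec$b_model,
    zero = rep(0, spec$n),
    constant = rep(spec$b_scale, spec$n),
    proportional = spec$b_scale * abs(a),
    halfnormal = abs(stats::rnorm(spec$n, 0, spec$b_scale))
  )
}

#' Draw one neutrosophic sample from a scenario
#'
#' Deterministic given the scenario's seed: the same spec always yields the
#' same sample.
#'
#' @param spec A [sim_scenario()].
#' @return A [neutro_sample()].
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  a <- draw_determinate(spec)
  neutro_sample(a, draw_b(spec, a), i = spec$i)
}

#' Run the Monte-Carlo experiment a scenario describes
#'
#' Draws `replicates` independent neutrosophic samples (one RNG substream per
#' replicate, all derived from the root seed), applies the neutrosophic JB
#' decision rule to each, and tallies the outcomes. Replicates whose realized
#' series is constant at an endpoint are counted as degenerate and excluded
#' from the rates, with a warning.
#'
#' @param spec A [sim_scenario()].
#' @return A one-row `SimulationReport` tibble: scenario echo (`n`, `dist`,
#'   `b_model`, `b_scale`, `i_lower`, `i_upper`, `alpha`, `seed`,
#'   `replicates`), decision counts (`n_accept`, `n_reject`,
#'   `n_indeterminate`, `n_degenerate`), the decision-based `reject_rate` and
#'   `indeterminate_rate`, endpoint-wise rejection rates
#'   (`reject_rate_lower`, `reject_rate_upper`), and the binomial Monte-Carlo
#'   standard error `mc_se` of `reject_rate`.
#' @examples
#' run_simulation(sim_scenario(n = 50, replicates = 200, seed = 7))
#' @export
run_simulation <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, spec$replicates)
  cv <- spec$critical_value %||%
    stats::qchisq(spec$alpha, df = 2, lower.tail = FALSE)

  decisions <- character(spec$replicates)
  rej_lower <- logical(spec$replicates)
  rej_upper <- logical(spec$replicates)
  for (r in seq_len(spec$replicates)) {
    set.seed(rep_seeds[[r]])
    a <- draw_determinate(spec)
    s <- neutro_sample(a, draw_b(spec, a), i = spec$i)
    jb <- tryCatch(neutro_jb(s), neutrojb_degenerate_error = function(e) NULL)
    if (is.null(jb)) {
      decisions[[r]] <- "degenerate"
      next
    }
    decisions[[r]] <- jb_decision(jb, alpha = spec$alpha,
                                  critical_value = cv)$decision
    rej_lower[[r]] <- jb$at_lower >= cv
    rej_upper[[r]] <- jb$at_upper >= cv
  }

  n_deg <- sum(decisions == "degenerate")
  if (n_deg > 0) {
    warning(n_deg, " degenerate replicate(s) excluded from rates.",
            call. = FALSE)
  }
  valid <- decisions != "degenerate"
  n_valid <- sum(valid)
  rate <- function(x) if (n_valid == 0) NA_real_ else x / n_valid
  n_rej <- sum(decisions == "reject")
  p_rej <- rate(n_rej)

  tibble::tibble(
    n = spec$n, dist = spec$dist, b_model = spec$b_model,
    b_scale = spec$b_scale, i_lower = spec$i[[1]], i_upper = spec$i[[2]],
    alpha = spec$alpha, seed = spec$seed, replicates = spec$replicates,
    critical_value = cv,
    n_accept = sum(decisions == "accept"),
    n_reject = n_rej,
    n_indeterminate = sum(decisions == "indeterminate"),
    n_degenerate = n_deg,
    reject_rate = p_rej,
    indeterminate_rate = rate(sum(decisions == "indeterminate")),
    reject_rate_lower = rate(sum(rej_lower[valid])),
    reject_rate_upper = rate(sum(rej_upper[valid])),
    mc_se = if (n_valid == 0) NA_real_ else sqrt(p_rej * (1 - p_rej) / n_valid)
  )
}

#' Estimate the empirical size of the test under a normal null
#'
#' Convenience wrapper around [run_simulation()] that insists the
#' determinate-part distribution is normal, so the rejection rate estimates
#' the type-I error of the test at the scenario's `alpha`.
#'
#' @param spec A [sim_scenario()] with `dist = "normal"`.
#' @return A `SimulationReport` tibble (see [run_simulation()]).
#' @export
estimate_size <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$dist != "normal") {
    stop("Size is defined under the normal null; use run_simulation() for ",
         "alternatives.", call. = FALSE)
  }
  run_simulation(spec)
}

#' Read a scenario from a YAML configuration file
#'
#' Keys mirror the arguments of [sim_scenario()]; `dist_args` may be a nested
#' mapping.
#'
#' @param path Path to a YAML file.
#' @return A `scenario_spec`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  # keep the key `n` (and friends) as strings: YAML 1.1 would read them as booleans
  keep <- function(x) x
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = keep, "bool#no" = keep))
  if (!is.list(cfg) || is.null(cfg$n)) {
    stop("Scenario file must define at least `n`.", call. = FALSE)
  }
  sim_scenario(
    n = cfg$n,
    dist = cfg$dist %||% "normal",
    dist_args = cfg$dist_args %||% list(),
    b_model = cfg$b_model %||% "zero",
    b_scale = cfg$b_scale %||% 0,
    i = unlist(cfg$i %||% c(0, 1)),
    replicates = cfg$replicates %||% 1000,
    alpha = cfg$alpha %||% 0.05,
    seed = cfg$seed %||% 1,
    critical_value = cfg$critical_value
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
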
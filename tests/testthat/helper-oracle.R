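# Independent naive-loop oracles for the classical moments and JB, kept
# deliberately separate from the package's vectorised implementations.

oracle_skew <- function(x) {
  n <- length(x)
  d <- x - sum(x) / n
  s <- sqrt(sum(d^2) / n)
  acc <- 0
  for (v in d) acc <- acc + v^3
  acc / (n * s^3)
}

oracle_ekurt <- function(x) {
  n <- length(x)
  d <- x - sum(x) / n
  s <- sqrt(sum(d^2) / n)
  acc <- 0
  for (v in d) acc <- acc + v^4
  acc / (n * s^4) - 3
}

oracle_jb <- function(x) {
  length(x) * (oracle_skew(x)^2 / 6 + oracle_ekurt(x)^2 / 24)
}

# Absolute-tolerance comparison, for values the source prints truncated to
# four decimals.
expect_within <- function(actual, expected, tol = 0.001) {
  expect_lt(max(abs(actual - expected)), tol)
}

# Worked-example data: three gold-mine centres, four observations each.
table1 <- list(
  G1 = list(a = c(0.32, 0.09, 0.22, 0.13), b = c(0.43, 0.15, 0.31, 0.44)),
  G2 = list(a = c(0.10, 0.13, 0.29, 0.08), b = c(0.18, 0.23, 0.32, 0.50)),
  G3 = list(a = c(0.22, 0.12, 0.28, 0.23), b = c(0.40, 0.10, 0.39, 0.40))
)

table1_sample <- function(g, i = c(0, 1)) {
  neutro_sample(table1[[g]]$a, table1[[g]]$b, i = i)
}

random_neutro_sample <- function(n = sample(3:50, 1)) {
  neutro_sample(stats::rnorm(n), stats::rexp(n),
                i = sort(abs(stats::rnorm(2))))
}
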
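test_that("realize evaluates z = a + b*i, preserving order", {
  s <- table1_sample("G1")
  expect_equal(realize(s, 0), c(0.32, 0.09, 0.22, 0.13))
  expect_equal(realize(s, 1)[1], 0.75)
  s0 <- neutro_sample(c(5, -2, 7), b = 0)
  for (i in c(-1, 0, 0.3, 10)) expect_equal(realize(s0, i), c(5, -2, 7))
  expect_error(realize(s, Inf), "finite")
  expect_error(realize(s, c(0, 1)), "single")
})

test_that("sample construction enforces finiteness and the indeterminacy interval", {
  expect_error(neutro_sample(numeric(0)), "nonempty")
  expect_error(neutro_sample(c(1, NA)), "finite")
  expect_error(neutro_sample(1:4, i = c(-0.1, 1)), "0 <= i_lower")
  expect_error(neutro_sample(1:4, i = c(0.5, 0.2)), "0 <= i_lower")
  expect_error(neutro_sample(1:4, i = c(0, Inf)), "finite")
  s <- neutro_sample(1:4, i = c(0, 0))
  expect_identical(s$i_lower, s$i_upper)
})

test_that("neutrosophic means match the worked-example values", {
  expect_equal(unlist(neutro_mean(table1_sample("G1"))),
               c(a_bar = 0.19, b_bar = 0.3325))
  expect_equal(unlist(neutro_mean(table1_sample("G2"))),
               c(a_bar = 0.15, b_bar = 0.3075))
  expect_equal(unlist(neutro_mean(table1_sample("G3"))),
               c(a_bar = 0.2125, b_bar = 0.3225))
  expect_equal(unlist(neutro_mean(neutro_sample(rep(3, 5), 0))),
               c(a_bar = 3, b_bar = 0))
})

test_that("realized mean at any i equals a_bar + b_bar * i", {
  withr::with_seed(11, {
    for (k in 1:25) {
      s <- random_neutro_sample()
      m <- neutro_mean(s)
      i <- stats::runif(1, -2, 2)
      expect_equal(mean(realize(s, i)), m$a_bar + m$b_bar * i, tolerance = 1e-12)
    }
  })
})

test_that("deviations reproduce the worked example and sum to zero at both endpoints", {
  d <- neutro_deviations(table1_sample("G1", i = c(0, 0.05)))
  expect_equal(d$at_lower[1], 0.13, tolerance = 1e-12)
  expect_within(d$at_upper[1], 0.1348)
  expect_equal(d$at_lower[4], -0.06, tolerance = 1e-12)
  expect_within(d$at_upper[4], -0.0546)
  withr::with_seed(21, {
    for (k in 1:25) {
      d <- neutro_deviations(random_neutro_sample())
      expect_lt(abs(sum(d$at_lower)), 1e-12)
      expect_lt(abs(sum(d$at_upper)), 1e-12)
    }
  })
})

test_that("sums of squares match the worked example at I = [0, 1]", {
  expected <- list(G1 = c(0.0314, 0.1338), G2 = c(0.0274, 0.0792),
                   G3 = c(0.0134, 0.1337))
  for (g in names(expected)) {
    ss <- neutro_ss(table1_sample(g))
    expect_within(c(ss$at_lower, ss$at_upper), expected[[g]])
    expect_gte(ss$at_lower, 0)
    expect_gte(ss$at_upper, 0)
  }
  const <- neutro_ss(neutro_sample(rep(2, 4), 0))
  expect_equal(c(const$at_lower, const$at_upper), c(0, 0))
})

test_that("standard deviation is sqrt(SS/n) and squares back to SS", {
  s <- table1_sample("G1")
  expect_within(neutro_std(s)$at_lower, sqrt(0.0314 / 4))
  expect_equal(c(0, 0), with(neutro_std(neutro_sample(rep(1, 3), 0)),
                             c(at_lower, at_upper)))
  withr::with_seed(31, {
    for (k in 1:25) {
      s <- random_neutro_sample()
      n <- length(s)
      ss <- neutro_ss(s)
      sd <- neutro_std(s)
      expect_equal(n * sd$at_lower^2, ss$at_lower, tolerance = 1e-12)
      expect_equal(n * sd$at_upper^2, ss$at_upper, tolerance = 1e-12)
    }
  })
})

test_that("skewness matches the worked-example lower endpoints and the i = 1 realization", {
  expect_within(neutro_skewness(table1_sample("G1"))$at_lower, 0.3623)
  expect_within(neutro_skewness(table1_sample("G3"))$at_lower, -0.6113)
  # upper endpoint is the classical skewness of the realized series a + b
  g1 <- table1$G1
  expect_equal(neutro_skewness(table1_sample("G1"))$at_upper,
               oracle_skew(g1$a + g1$b), tolerance = 1e-12)
  sym <- neutro_sample(c(-1, 1, -1, 1), 0)
  expect_equal(neutro_skewness(sym)$at_lower, 0)
  expect_equal(neutro_skewness(sym)$at_upper, 0)
})

test_that("excess kurtosis matches the worked-example lower endpoints and its floor", {
  expect_within(neutro_excess_kurtosis(table1_sample("G1"))$at_lower, -1.3797)
  expect_within(neutro_excess_kurtosis(table1_sample("G2"))$at_lower, -0.7911)
  two_point <- neutro_excess_kurtosis(neutro_sample(c(-1, 1, -1, 1), 0))
  expect_equal(two_point$at_lower, -2)
  expect_equal(two_point$at_upper, -2)
})

test_that("degenerate realized series raise a typed error naming the endpoint", {
  # b = -a collapses the series to a constant at i = 1 only
  s <- neutro_sample(c(1, 2, 3, 4), b = -c(1, 2, 3, 4) + 2.5, i = c(0, 1))
  expect_equal(realize(s, 1), rep(2.5, 4))
  err <- expect_error(neutro_skewness(s), class = "neutrojb_degenerate_error")
  expect_match(conditionMessage(err), "upper")
  err <- expect_error(neutro_excess_kurtosis(neutro_sample(rep(1, 5), 1)),
                      class = "neutrojb_degenerate_error")
  expect_match(conditionMessage(err), "lower")
  expect_error(neutro_skewness(neutro_sample(c(1, 2), 0)), "n >= 3")
})

test_that("all moments reduce exactly to classical values when b = 0 or I_L = I_U", {
  withr::with_seed(41, {
    for (k in 1:40) {
      x <- stats::rnorm(sample(3:30, 1))
      for (s in list(neutro_sample(x, 0),
                     neutro_sample(x, stats::rexp(length(x)), i = c(0, 0)))) {
        for (f in list(neutro_ss, neutro_std, neutro_skewness,
                       neutro_excess_kurtosis)) {
          r <- f(s)
          expect_identical(r$at_lower, r$at_upper)
        }
        expect_equal(neutro_skewness(s)$at_lower, oracle_skew(x),
                     tolerance = 1e-12)
        expect_equal(neutro_ss(s)$at_lower, sum((x - mean(x))^2),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("moments agree with naive-loop oracles on random samples", {
  withr::with_seed(51, {
    for (k in 1:200) {
      s <- random_neutro_sample()
      for (i in c(s$i_lower, s$i_upper)) {
        z <- realize(s, i)
        at <- if (i == s$i_lower) "at_lower" else "at_upper"
        expect_equal(neutro_ss(s)[[at]], sum((z - mean(z))^2), tolerance = 1e-10)
        expect_equal(neutro_skewness(s)[[at]], oracle_skew(z), tolerance = 1e-10)
        expect_equal(neutro_excess_kurtosis(s)[[at]], oracle_ekurt(z),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("moments agree with e1071 type-1 estimators", {
  skip_if_not_installed("e1071")
  withr::with_seed(61, {
    for (k in 1:50) {
      z <- realize(random_neutro_sample(), 1)
      s <- neutro_sample(z)
      expect_equal(neutro_skewness(s)$at_lower, e1071::skewness(z, type = 1),
                   tolerance = 1e-10)
      expect_equal(neutro_excess_kurtosis(s)$at_lower,
                   e1071::kurtosis(z, type = 1), tolerance = 1e-10)
    }
  })
})

test_that("realized moments satisfy the Pearson bounds", {
  withr::with_seed(71, {
    for (k in 1:100) {
      s <- random_neutro_sample()
      for (at in c("at_lower", "at_upper")) {
        ek <- neutro_excess_kurtosis(s)[[at]]
        sk <- neutro_skewness(s)[[at]]
        expect_gte(ek, -2)
        expect_lte(sk^2, (ek + 3) - 1 + 1e-10)
      }
    }
  })
})

test_that("deviations and higher moments are invariant to shifting all a values", {
  withr::with_seed(81, {
    for (k in 1:25) {
      s <- random_neutro_sample()
      shift <- stats::rnorm(1, sd = 100)
      s2 <- neutro_sample(s$a + shift, s$b, i = c(s$i_lower, s$i_upper))
      expect_equal(neutro_deviations(s), neutro_deviations(s2), tolerance = 1e-8)
      expect_equal(neutro_ss(s)$at_upper, neutro_ss(s2)$at_upper, tolerance = 1e-8)
      expect_equal(neutro_skewness(s)$at_lower, neutro_skewness(s2)$at_lower,
                   tolerance = 1e-8)
      expect_equal(neutro_excess_kurtosis(s)$at_upper,
                   neutro_excess_kurtosis(s2)$at_upper, tolerance = 1e-8)
    }
  })
})

test_that("neutro_interval keeps endpoint correspondence plus a sorted view", {
  x <- neutro_interval(2, -1)
  expect_equal(x$at_lower, 2)
  expect_equal(x$at_upper, -1)
  expect_equal(x$min, -1)
  expect_equal(x$max, 2)
  expect_equal(as_tibble(x)$min, -1)
})

test_that("neutro_describe reports one row per group in file order", {
  desc <- neutro_describe(gold_mines(), group = "group")
  expect_equal(desc$group, c("G1", "G2", "G3"))
  expect_equal(desc$n, rep(4, 3))
  expect_equal(desc$a_bar, c(0.19, 0.15, 0.2125))
  expect_within(desc$skew_lower, c(0.3623, 1.0001, -0.6113))
})
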
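# Population variance with bootstrap CIs, scrambling tests, level
# comparisons, outlier screening, and the variance-component decomposition.

test_that("population variance handles degenerate and small inputs", {
  pv <- population_variance(rep(0.2, 10), n_boot = 100, seed = 1)
  expect_equal(pv$s2, 0)
  expect_equal(c(pv$ci_lo, pv$ci_hi), c(0, 0))
  expect_error(population_variance(c(0.1, 0.2)), "at least 3")
})

test_that("bootstrap CIs bracket the point estimate in both methods", {
  set.seed(14)
  for (method in c("studentized", "percentile")) {
    for (i in 1:10) {
      x <- rnorm(25, 0.2, 0.06)
      pv <- population_variance(x, n_boot = 500, seed = i, method = method)
      expect_lte(pv$ci_lo, pv$s2)
      expect_gte(pv$ci_hi, pv$s2)
      expect_gte(pv$ci_lo, 0)
    }
  }
})

test_that("population variance estimates are rotation invariant", {
  set.seed(15)
  x <- rnorm(20, 0.1, 0.05)
  a <- population_variance(x, n_boot = 200, seed = 3)
  b <- population_variance(x + 0.37, n_boot = 200, seed = 3)
  expect_equal(a$s2, b$s2, tolerance = 1e-12)
  expect_equal(a$ci_lo, b$ci_lo, tolerance = 1e-10)
})

test_that("scrambling leaves identical populations at chance", {
  d <- rep(0.21, 12)
  rt <- repetition_test(d, d, n_scramble = 200, seed = 5)
  expect_equal(rt$p, 0.5)
  expect_equal(rt$observed, 0)
})

test_that("strong animal identity yields very small repetition p values", {
  set.seed(16)
  n <- 24
  A <- rnorm(n, 0.2, sigma_for(0.004))
  d1 <- A + rnorm(n, 0, sigma_for(0.0001))
  d2 <- A + rnorm(n, 0, sigma_for(0.0001))
  rt <- repetition_test(d1, d2, n_scramble = 2000, seed = 6)
  expect_lt(rt$p, 0.005)
  expect_lt(rt$observed, rt$null_mean)
  # both scrambling schemes agree qualitatively
  rt2 <- repetition_test(d1, d2, n_scramble = 2000, seed = 6,
                         scheme = "repair")
  expect_lt(rt2$p, 0.005)
})

test_that("bilateral test separates mirrored from independent sides", {
  set.seed(17)
  n <- 26
  A <- rnorm(n, 0.2, sigma_for(0.004))
  mirrored <- bilateral_test(A + rnorm(n, 0, 0.002),
                             A + rnorm(n, 0, 0.002),
                             n_scramble = 2000, seed = 7)
  expect_lt(mirrored$p, 0.01)
  indep <- bilateral_test(rnorm(n, 0.2, sigma_for(0.004)),
                          rnorm(n, 0.2, sigma_for(0.004)),
                          n_scramble = 2000, seed = 8)
  expect_gt(indep$p, 0.05)
  expect_error(bilateral_test(0.1, 0.2), "at least 5")
  expect_message(repetition_test(c(0.1, NA, 0.2, 0.3, 0.15, 0.18),
                                 c(0.1, 0.2, 0.2, 0.3, 0.15, 0.18),
                                 n_scramble = 50, seed = 1), "dropped")
})

test_that("level comparison is exact for identical groups and rotation invariant", {
  a <- c(0.21, 0.23, 0.19, 0.25)
  lc <- compare_levels(a, a, paired = TRUE)
  expect_equal(lc$p.value, 1)
  expect_equal(lc$statistic, 0)

  set.seed(18)
  x <- rnorm(12, 0.23, 0.05)
  y <- rnorm(12, 0.13, 0.05)
  l1 <- compare_levels(x, y)
  l2 <- compare_levels(x + 0.4, y + 0.4)  # rotate both groups
  expect_equal(l1$p.value, l2$p.value, tolerance = 1e-9)
  expect_lt(l1$p.value, 0.01)
  expect_equal(l1$mean_a, mean(x), tolerance = 0.01)
  expect_error(compare_levels(0.1, c(0.1, 0.2)), "at least 2")
  expect_error(compare_levels(c(0.1, 0.2, 0.3), c(0.1, 0.2), paired = TRUE),
               "equal length")
})

test_that("outlier screening applies the 1.5 IQR whisker rule", {
  expect_false(any(outlier_screen(c(0.1, 0.11, 0.12, 0.13, 0.12))))
  flags <- outlier_screen(c(0.1, 0.11, 0.12, 0.13, 0.12, 0.5))
  expect_identical(which(flags), 6L)
  expect_error(outlier_screen(c(1, 2, 3)), "at least 4")
})

test_that("variance components are recovered from model-generated strata", {
  set.seed(19)
  n <- 300
  v <- c(pop = 0.004, bil = 0.005, rep = 0.001, cyc = 0.001)
  n_cyc <- 40
  rows <- list()
  for (a in seq_len(n)) {
    A <- rnorm(1, 0.2, sigma_for(v["pop"]))
    for (s in c("L", "R")) {
      S <- rnorm(1, 0, sigma_for(v["bil"]))
      for (k in 1:2) {
        R <- rnorm(1, 0, sigma_for(v["rep"]))
        eps <- rnorm(n_cyc, 0, sigma_for(v["cyc"]))
        d <- A + S + R + eps
        rows[[length(rows) + 1]] <- data.frame(
          animal = a, side = s, level = "cpg", coordination = "peristaltic",
          switch_cycle = k, mean_dphi = wrap_phase(mean(d)),
          s2_cycle = angular_variance(d), n_cycles = n_cyc)
      }
    }
  }
  est <- estimate_variance_components(do.call(rbind, rows))
  expect_equal(est$var_cycle, unname(v["cyc"]), tolerance = 0.15)
  expect_equal(est$var_repetition, unname(v["rep"]), tolerance = 0.2)
  expect_equal(est$var_bilateral, unname(v["bil"]), tolerance = 0.2)
  expect_equal(est$var_population, unname(v["pop"]), tolerance = 0.25)
})
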
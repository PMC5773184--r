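# Burst grouping, phase computation, cycle pairing, and MRR markers.

test_that("bursts are grouped at the interburst-interval threshold", {
  b <- group_bursts(c(0, 0.1, 0.2, 2.0, 2.1, 2.2), ibi_threshold = 1)
  expect_length(b$middles, 2)
  expect_equal(b$middles, c(0.1, 2.1))
  expect_equal(b$periods, 2.0)

  # stray-spike elimination: a lone spike is not a burst
  b2 <- group_bursts(c(0, 0.1, 0.2, 5.0), min_spikes = 3)
  expect_length(b2$middles, 1)
  expect_equal(b2$middles, 0.1)

  # single burst: no periods
  b3 <- group_bursts(c(0, 0.1, 0.2))
  expect_length(b3$periods, 0)

  expect_warning(group_bursts(c(0, 5, 10), min_spikes = 3), "no burst")
  expect_error(group_bursts(numeric(0)), "at least one")
  expect_error(group_bursts(c(1, 1)), "strictly increasing")
})

test_that("middle spike is the ceiling(n/2)-th spike", {
  b <- group_bursts(c(1, 2, 3, 4), ibi_threshold = 10, min_spikes = 2)
  expect_equal(b$middles, 2)  # even count: earlier central spike
  b5 <- group_bursts(c(1, 2, 3, 4, 5), ibi_threshold = 10, min_spikes = 2)
  expect_equal(b5$middles, 3)
})

test_that("burst grouping is idempotent and translation invariant", {
  set.seed(5)
  for (i in 1:20) {
    spk <- sort(runif(60, 0, 100))
    b1 <- group_bursts(spk, ibi_threshold = 0.8, min_spikes = 2)
    again <- group_bursts(unlist(b1$spikes), ibi_threshold = 0.8,
                          min_spikes = 2)
    expect_equal(again$middles, b1$middles)
    expect_equal(lengths(again$spikes), lengths(b1$spikes))
    shifted <- group_bursts(spk + 13.7, ibi_threshold = 0.8, min_spikes = 2)
    expect_equal(shifted$middles, b1$middles + 13.7)
  }
})

test_that("phase_of reduces to [0,1) and is period-translation invariant", {
  expect_equal(phase_of(5, 5, 8), 0)
  expect_equal(phase_of(9, 5, 8), 0.5)
  expect_equal(phase_of(5 - 0.8, 5, 8), 0.9, tolerance = 1e-12)
  expect_equal(wrap_phase(phase_of(5 - 0.8, 5, 8)), -0.1, tolerance = 1e-12)
  expect_error(phase_of(1, 0, 0), "positive")
  set.seed(6)
  for (i in 1:30) {
    ti <- runif(1, 0, 100); tr <- runif(1, 0, 100); Tr <- runif(1, 1, 10)
    k <- sample(-5:5, 1)
    expect_equal(phase_of(ti + k * Tr, tr, Tr), phase_of(ti, tr, Tr),
                 tolerance = 1e-9)
  }
})

test_that("pair_cycles matches target markers to half-open reference cycles", {
  ref <- group_bursts(as.numeric(sapply(seq(5, 85, by = 8),
                                        function(m) m + c(-0.2, 0, 0.2))))
  # identical series: all dphi exactly 0
  ps0 <- pair_cycles(ref, ref)
  expect_true(all(ps0$dphi == 0))
  # constant shift by 0.2 of the (constant) period
  tgt <- group_bursts(as.numeric(sapply(seq(5, 85, by = 8) + 0.2 * 8,
                                        function(m) m + c(-0.2, 0, 0.2))))
  ps <- pair_cycles(ref, tgt)
  expect_equal(ps$dphi[!is.na(ps$dphi)], rep(0.2, sum(!is.na(ps$dphi))),
               tolerance = 1e-12)
})

test_that("pair_cycles flags cycles with zero or multiple target markers", {
  mids <- seq(5, 85, by = 8)
  ref <- group_bursts(as.numeric(sapply(mids, function(m) m + c(-0.2, 0, 0.2))))
  tgt_mids <- mids[-4] + 1.6   # one target burst missing
  tgt <- group_bursts(as.numeric(sapply(tgt_mids,
                                        function(m) m + c(-0.2, 0, 0.2))))
  expect_message(ps <- pair_cycles(ref, tgt), "skipped")
  expect_equal(sum(is.na(ps$phi)), 1)
  expect_equal(ps$n_target[ps$cycle == 4], 0)
  expect_equal(sum(!is.na(ps$phi)), length(mids) - 2)

  expect_error(pair_cycles(group_bursts(c(1, 1.1, 1.2)), tgt), "two reference")
  far <- group_bursts(c(1000, 1000.1, 1000.2))
  expect_error(pair_cycles(ref, far), "overlap")
})

test_that("MRR markers are recovered from constriction-like traces", {
  # pure sinusoid: steepest rises exactly one period apart
  tt <- seq(0, 80, by = 0.05)
  tr <- data.frame(time = tt, value = sin(2 * pi * (tt - 2) / 8))
  ev <- mrr_phase_markers(tr, smoothing = 1)
  expect_gt(length(ev), 5)
  expect_equal(diff(ev), rep(8, length(ev) - 1), tolerance = 0.051)

  # generator ground truth, noise-free: within one sample
  cfg <- noiseless_config(dphi_peri = 0.25, n_animals = 1)
  ct <- generate_constriction_traces(cfg, fs = 20)
  key <- "A001_L_12"
  truth <- ct$markers[ct$markers$animal == "A001" & ct$markers$side == "L" &
                        ct$markers$segment == "12", "t_mrr"]
  ev2 <- mrr_phase_markers(ct$traces[[key]], smoothing = 5)
  matched <- vapply(truth, function(m) min(abs(ev2 - m)), 0)
  expect_lt(max(matched), 1 / 20 + 1e-9)

  # with additive noise: still within one sample after smoothing
  set.seed(9)
  noisy <- ct$traces[[key]]
  noisy$value <- noisy$value + rnorm(nrow(noisy), 0, 0.01)
  ev3 <- mrr_phase_markers(noisy, smoothing = 5)
  expect_length(ev3, length(truth))
  matched3 <- vapply(truth, function(m) min(abs(ev3 - m)), 0)
  expect_lt(max(matched3), 1 / 20 + 1e-9)

  expect_warning(flat <- mrr_phase_markers(data.frame(time = tt, value = 1)),
                 "flat")
  expect_length(flat, 0)
})
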
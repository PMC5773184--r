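# The hierarchical synthetic-recording generator: exactness in the
# noise-free limit, variance realization, episode structure, determinism.

test_that("noise-free recordings realize the target phase exactly", {
  cfg <- noiseless_config(dphi_peri = 0.2, dphi_sync = 0.2, n_animals = 1)
  pop <- generate_population(cfg)
  tr <- pop$recordings[[1]]$trains
  ps <- pair_cycles(group_bursts(tr[["A001_L_HN4"]]),
                    group_bursts(tr[["A001_L_HN7"]]))
  expect_true(all(!is.na(ps$dphi)))
  expect_equal(ps$dphi, rep(0.2, nrow(ps)), tolerance = 1e-9)
})

test_that("per-cycle noise realizes the configured angular variance", {
  # oracle: the wrapped-normal relation, checked by brute-force sampling
  v <- 0.002
  set.seed(41)
  oracle <- angular_variance(rwrapnorm(2e5, 0, v))
  expect_equal(oracle, v, tolerance = 0.02)

  cfg <- generator_config(
    n_animals = 2, var_population = 0, var_bilateral = 0,
    var_repetition = 0, var_cycle = v, cycles_per_episode = c(55, 60),
    n_switch_cycles = 4, seed = 13)
  pop <- generate_population(cfg)
  tr <- pop$recordings[[1]]$trains
  ps <- suppressMessages(pair_cycles(group_bursts(tr[["A001_L_HN4"]]),
                                     group_bursts(tr[["A001_L_HN7"]])))
  truth <- pop$truth$cycles
  cyc <- truth[truth$animal == "A001" & truth$side == "L" &
                 truth$level == "cpg", ]
  # measured matches truth cycle by cycle ...
  m <- merge(ps, cyc, by = "cycle")
  # a marker with a negative centered phase lies, by the half-open cycle
  # rule, in the preceding reference cycle; compare where the marker stays
  # in its own cycle
  m <- m[!is.na(m$dphi.x) & m$dphi.y >= 0, ]
  expect_gt(nrow(m), 200)
  expect_lt(max(abs(wrap_phase(m$dphi.x - m$dphi.y))), 1e-9)
  # ... and pooled per-coordination variance recovers var_cycle
  for (co in c("peristaltic", "synchronous")) {
    d <- cyc$dphi[cyc$coordination == co]
    expect_equal(angular_variance(wrap_phase(d - mean(d))), v,
                 tolerance = 0.25)
  }
})

test_that("episode lengths respect the configured range", {
  cfg <- generator_config(n_animals = 5, cycles_per_episode = c(15, 60),
                          seed = 3)
  pop <- generate_population(cfg)
  ep <- pop$truth$episodes
  expect_true(all(ep$n_cycles >= 15 & ep$n_cycles <= 60))
  expect_equal(nrow(ep), 5 * 4)  # 2 switch cycles = 4 episodes per animal
  # episodes partition the cycle range
  for (an in unique(ep$animal)) {
    e <- ep[ep$animal == an, ]
    expect_equal(e$first_cycle, c(1, head(e$last_cycle, -1) + 1))
  }
})

test_that("the two sides are always in opposite coordinations", {
  pop <- generate_population(quick_config(seed = 17))
  ep <- pop$truth$episodes
  expect_true(all(ep$coordination_left != ep$coordination_right))
  cyc <- pop$truth$cycles
  byc <- split(cyc$coordination, list(cyc$animal, cyc$cycle, cyc$level),
               drop = TRUE)
  expect_true(all(vapply(byc, function(x) length(unique(x)) == 2, TRUE)))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- quick_config(seed = 23)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$truth$cycles, p2$truth$cycles)
  expect_identical(p1$recordings[[2]]$trains[[3]]$times,
                   p2$recordings[[2]]$trains[[3]]$times)
})

test_that("invalid generator settings are rejected", {
  expect_error(generator_config(period_cv = 0.3), "period_cv")
  expect_error(generator_config(var_population = 0.02, var_bilateral = 0.02,
                                var_cycle = 0.01),
               "dispersion too large")
  expect_error(generator_config(dphi_mean = list(
    cpg = c(peristaltic = 1.2, synchronous = 0),
    motor = c(peristaltic = 0.1, synchronous = 0))), "dphi_mean")
  expect_error(generator_config(cycles_per_episode = c(10, 5)), "range")
})

test_that("constriction traces place the maximum rate of rise on target", {
  cfg <- noiseless_config(dphi_peri = 0.25, dphi_sync = 0.25, n_animals = 1)
  ct <- generate_constriction_traces(cfg, fs = 25)
  mk <- ct$markers
  ref <- mk[mk$side == "L" & mk$segment == "8", "t_mrr"]
  tgt <- mk[mk$side == "L" & mk$segment == "12", "t_mrr"]
  # target MRR sits exactly a quarter period after the reference marker
  expect_equal(tgt, ref[seq_along(tgt)] + 0.25 * 8, tolerance = 1e-9)
  # and the trace's steepest rise is found there
  ev <- mrr_phase_markers(ct$traces[["A001_L_12"]], smoothing = 3)
  matched <- vapply(tgt, function(m) min(abs(ev - m)), 0)
  expect_lt(max(matched), 1 / 25 + 1e-9)

  expect_error(generate_constriction_traces(cfg, fs = 1), "too low")
  expect_error(generate_constriction_traces(cfg, amplitude = 0),
               "zero-amplitude")
})

test_that("clamp traces obey Ohmic scaling and reject bad inputs", {
  tr <- generate_clamp_trace(1, strengths = 2, holding = -42, reversal = -62)
  expect_equal(max(tr$current), 2 * 20, tolerance = 1e-6)  # 40 pA
  expect_equal(min(tr$current), 0)

  flat <- generate_clamp_trace(list(1, 2), strengths = c(0, 0), holding = -42)
  expect_true(all(flat$current == 0))

  expect_error(generate_clamp_trace(1, strengths = -1, holding = -42),
               "nonnegative")
  expect_error(generate_clamp_trace(1, strengths = 1, holding = -62,
                                    reversal = -62), "differ")
})

test_that("per-unit STAs separate two interleaved presynaptic units", {
  t4 <- regular_triggers(n_bursts = 15, t0 = 2)
  t7 <- regular_triggers(n_bursts = 15, t0 = 6.5)
  tr <- generate_clamp_trace(list(t4, t7), strengths = c(1, 3),
                             holding = -42)
  g4 <- to_conductance(spike_triggered_average(tr, t4)$peak_pA, -42)$g
  g7 <- to_conductance(spike_triggered_average(tr, t7)$peak_pA, -42)$g
  expect_equal(proportional_strength(g4, g7), 0.25, tolerance = 0.02)
})
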
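# Episode classification and switch-cycle assembly.

test_that("a recording without switches is one episode pair", {
  set.seed(2)
  left <- make_phase_series(rnorm(30, 0.2, 0.01))
  right <- make_phase_series(rnorm(30, 0.02, 0.01))
  es <- classify_episodes(left, right)
  expect_equal(nrow(es$episodes), 1)
  expect_equal(es$episodes$coordination_left, "peristaltic")
  expect_equal(es$episodes$coordination_right, "synchronous")
  expect_true(all(!es$cycles$transitional))
})

test_that("episode boundaries match generator ground truth", {
  cfg <- generator_config(n_animals = 4, n_switch_cycles = 3, seed = 19)
  pop <- generate_population(cfg)
  hyster <- 3
  for (rec in pop$recordings[1:3]) {
    tr <- rec$trains
    an <- rec$animal
    psL <- suppressMessages(pair_cycles(group_bursts(tr[[paste0(an, "_L_HN4")]]),
                                        group_bursts(tr[[paste0(an, "_L_HN7")]])))
    psR <- suppressMessages(pair_cycles(group_bursts(tr[[paste0(an, "_R_HN4")]]),
                                        group_bursts(tr[[paste0(an, "_R_HN7")]])))
    es <- classify_episodes(psL, psR, hysteresis = hyster)
    truth <- pop$truth$episodes[pop$truth$episodes$animal == an, ]
    # 5 switches delimit the truth's 6 episodes; boundaries within hysteresis
    expect_equal(nrow(es$episodes), nrow(truth))
    expect_true(all(abs(es$episodes$first_cycle - truth$first_cycle) <= hyster))
    expect_equal(es$episodes$coordination_left, truth$coordination_left)
    # complementary labels at every cycle
    expect_true(all(es$cycles$left != es$cycles$right))
  }
})

test_that("single-cycle excursions never produce a switch", {
  d <- rep(0.02, 30); d[15] <- 0.4
  left <- make_phase_series(d)
  right <- make_phase_series(rep(0.2, 30))
  es <- classify_episodes(left, right, hysteresis = 3)
  expect_equal(nrow(es$episodes), 1)
  expect_equal(es$episodes$coordination_left, "synchronous")
})

test_that("an absolute threshold flags ambiguous coordination", {
  set.seed(3)
  left <- make_phase_series(rnorm(30, 0.05, 0.005))
  right <- make_phase_series(rnorm(30, 0.04, 0.005))
  expect_error(classify_episodes(left, right, threshold = 0.12),
               "ambiguous")
  # a threshold between the two states is fine
  left2 <- make_phase_series(rnorm(30, 0.2, 0.005))
  right2 <- make_phase_series(rnorm(30, 0.02, 0.005))
  es <- classify_episodes(left2, right2, threshold = 0.11)
  expect_equal(nrow(es$episodes), 1)
})

test_that("cycles around a switch are marked transitional", {
  d <- c(rep(0.2, 20), rep(0.02, 20))
  left <- make_phase_series(d)
  right <- make_phase_series(rev(d))
  es <- classify_episodes(left, right, hysteresis = 3)
  expect_equal(nrow(es$episodes), 2)
  expect_equal(sum(es$cycles$transitional), 6)  # hysteresis on both sides
  expect_true(all(which(es$cycles$transitional) %in% 18:23))
})

test_that("switch cycles pair consecutive episodes without overlap", {
  ep3 <- data.frame(episode = 1:3,
                    coordination_left = c("peristaltic", "synchronous",
                                          "peristaltic"),
                    coordination_right = c("synchronous", "peristaltic",
                                           "synchronous"))
  sw <- build_switch_cycles(ep3, side = "L")
  expect_equal(sum(sw$complete), 1)
  expect_equal(nrow(sw), 2)  # one complete pair plus flagged remainder
  expect_false(sw$complete[2])

  # five complete episodes (six switches observed): two complete switch
  # cycles per side plus a remainder
  ep5 <- data.frame(episode = 1:5,
                    coordination_left = rep(c("peristaltic", "synchronous"),
                                            length.out = 5),
                    coordination_right = rep(c("synchronous", "peristaltic"),
                                             length.out = 5))
  sw5 <- build_switch_cycles(ep5)
  expect_equal(sum(sw5$complete[sw5$side == "L"]), 2)
  expect_equal(sum(!sw5$complete[sw5$side == "L"]), 1)

  ep1 <- ep3[1, ]
  expect_warning(sw1 <- build_switch_cycles(ep1, side = "L"), "fewer than two")
  expect_equal(nrow(sw1), 0)
})
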
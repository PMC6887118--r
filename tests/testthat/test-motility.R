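test_that("motility classes follow the displacement rules", {
  flat <- trace_track(rep(10, 30))
  expect_equal(classify_motility(flat)$class, "stalled")

  # 0.9 um oscillation, zero net displacement: not transported
  osc <- trace_track(10 + 0.45 * rep(c(0, 1, 0, -1), 8)[1:30])
  expect_equal(classify_motility(osc)$class, "oscillating")

  mono <- trace_track(10 + c(rep(0, 10), cumsum(rep(0.3, 5)), rep(1.5, 15)))
  expect_equal(classify_motility(mono)$class, "transported")

  short <- trace_track(rep(10, 10))
  expect_equal(classify_motility(short)$class, "unclassifiable")
})

test_that("a 6 s pause splits a run; shorter pauses do not", {
  steps <- c(rep(0.5, 5), rep(0, 2), rep(0.5, 5))  # 2 frames = 6 s pause
  tr <- trace_track(10 + cumsum(c(0, steps)))
  runs <- extract_runs(tr)
  expect_equal(nrow(runs), 2)

  steps1 <- c(rep(0.5, 5), 0, rep(0.5, 5))         # 3 s: same run
  runs1 <- extract_runs(trace_track(10 + cumsum(c(0, steps1))))
  expect_equal(nrow(runs1), 1)
})

test_that("run length sums distance regardless of direction", {
  steps <- c(rep(0.5, 4), rep(-0.5, 3))  # +2.0 then -1.5, no pause
  runs <- extract_runs(trace_track(10 + cumsum(c(0, steps))))
  expect_equal(nrow(runs), 1)
  expect_equal(runs$run_length, 3.5)
  expect_equal(runs$net_displacement, 0.5)
  expect_equal(runs$n_switches, 1)
})

test_that("run decomposition matches a brute-force pause-scanning oracle", {
  set.seed(101)
  for (i in 1:200) {
    tr <- random_trace()
    a <- extract_runs(tr)
    b <- oracle_runs(tr)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) {
      expect_equal(a$run_length, b$run_length, tolerance = 1e-9)
      expect_equal(a$net_displacement, b$net_displacement, tolerance = 1e-9)
      expect_equal(a$n_switches, b$n_switches)
      # invariant: summed distance bounds net displacement
      expect_true(all(a$run_length >= abs(a$net_displacement) - 1e-12))
      mono <- a$n_switches == 0
      expect_equal(a$run_length[mono], abs(a$net_displacement[mono]),
                   tolerance = 1e-9)
    }
  }
})

test_that("bout velocities equal displacement over elapsed time", {
  tr <- trace_track(10 + cumsum(c(0, rep(0.3, 10))))  # 3 um in 10 steps
  b <- run_velocity(tr)
  expect_equal(nrow(b), 1)
  expect_equal(b$velocity_um_s, 0.1)

  tr2 <- trace_track(10 + cumsum(c(0, rep(0.4 * 3, 8))))
  expect_equal(run_velocity(tr2)$velocity_um_s, 0.4, tolerance = 1e-9)

  none <- run_velocity(trace_track(rep(10, 10)))
  expect_equal(nrow(none), 0)
})

test_that("percent time moving reflects the scripted duty cycle", {
  always <- trace_track(10 + cumsum(c(0, rep(0.5, 20))))
  expect_equal(percent_time_moving(always, "anterograde"), 100)
  expect_equal(percent_time_moving(always, "retrograde"), 0)

  half <- trace_track(10 + cumsum(c(0, rep(c(0.5, 0), 10))))
  expect_equal(percent_time_moving(half), 50)

  duty3 <- rep(c(0.5, 0, 0, 0.5, 0, 0, 0, 0, 0, 0.5), 6)  # 30% of steps
  expect_equal(percent_time_moving(trace_track(10 + cumsum(c(0, duty3)))),
               30, tolerance = 2)
})

test_that("switch fraction counts runs with any direction change", {
  r0 <- data.frame(n_switches = c(0, 0, 0))
  expect_equal(switch_fraction(r0), 0)
  r1 <- data.frame(n_switches = c(0, 2))
  expect_equal(switch_fraction(r1), 0.5)
  expect_error(switch_fraction(r1[0, ]), "no runs")
})

test_that("simulated run switch probability is recovered by the analyzer", {
  cfg <- sim_config(axon_length = 3200, n_mito = 40, n_frames = 241,
                    frac_moving = 1, frac_oscillating = 0,
                    fission_prob_per_10min = 0, fusion_prob_per_10min = 0,
                    patch_rate = 0, drp1_rate = 0, run_switch_prob = 0.55,
                    seed = 3)
  tr <- simulate_dynamics(cfg)
  runs <- do.call(rbind, lapply(unique(tr$tracks$track), function(id) {
    extract_runs(tr$tracks[tr$tracks$track == id, ], cfg$frame_interval)
  }))
  # runs still in progress at the end of the movie are censored
  runs <- runs[runs$end_frame < cfg$n_frames - 1, ]
  n <- nrow(runs)
  expect_gte(n, 200)
  ci <- stats::qbinom(c(0.025, 0.975), n, 0.55) / n
  frac <- switch_fraction(runs)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})
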
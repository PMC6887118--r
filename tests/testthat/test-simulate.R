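test_that("rate-zero and determinism contracts hold", {
  cfg <- sim_config(fission_prob_per_10min = 0, fusion_prob_per_10min = 0,
                    seed = 5)
  tr <- simulate_dynamics(cfg)
  expect_equal(nrow(tr$fission_events), 0)
  expect_equal(nrow(tr$fusion_events), 0)

  cfg2 <- sim_config(seed = 9)
  a <- simulate_dynamics(cfg2)
  b <- simulate_dynamics(cfg2)
  expect_identical(a$fission_events, b$fission_events)
  expect_identical(a$fusion_events, b$fusion_events)
  expect_identical(a$tracks, b$tracks)
  c <- simulate_dynamics(sim_config(seed = 10))
  expect_false(identical(a$tracks, c$tracks))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(fission_prob_per_10min = 1.2), "probabilities")
  expect_error(sim_config(frame_interval = 0), "frame_interval")
  expect_error(sim_config(pixel_size = -1), "pixel_size")
  # axon too short for the requested mitochondria
  cfg <- sim_config(axon_length = 10, n_mito = 20, seed = 1)
  expect_error(simulate_dynamics(cfg), "too short")
  expect_equal(stack_width(sim_config(axon_length = 60, pixel_size = 0.12)),
               500L)
})

test_that("simulated fission fraction falls in the exact binomial CI", {
  n <- 300
  p <- 0.3
  cfg <- sim_config(axon_length = 1700, n_mito = n, n_frames = 201,
                    frac_moving = 0, frac_oscillating = 0,
                    fusion_prob_per_10min = 0, patch_rate = 0,
                    drp1_rate = 0, fission_prob_per_10min = p, seed = 21)
  tr <- simulate_dynamics(cfg)
  fissioned <- length(intersect(unique(tr$fission_events$parent), 1:n))
  ci <- stats::qbinom(c(0.025, 0.975), n, p)
  expect_gte(fissioned, ci[1])
  expect_lte(fissioned, ci[2])
})

test_that("length is conserved exactly at fission and fusion in truth", {
  cfg <- sim_config(seed = 33, fusion_prob_per_10min = 0.4,
                    frac_moving = 0.3, n_frames = 150)
  tr <- simulate_dynamics(cfg)
  len_at <- function(id, frame) {
    r <- tr$tracks[tr$tracks$track == id & tr$tracks$frame == frame, ]
    r$end - r$start
  }
  for (i in seq_len(nrow(tr$fission_events))) {
    ev <- tr$fission_events[i, ]
    expect_equal(len_at(ev$child1, ev$frame) + len_at(ev$child2, ev$frame),
                 len_at(ev$parent, ev$frame - 1L), tolerance = 1e-12)
    par <- tr$tracks[tr$tracks$track == ev$parent &
                       tr$tracks$frame == ev$frame - 1L, ]
    expect_gte(ev$position, par$start)
    expect_lte(ev$position, par$end)
  }
  for (i in seq_len(nrow(tr$fusion_events))) {
    ev <- tr$fusion_events[i, ]
    expect_equal(len_at(ev$child, ev$frame),
                 len_at(ev$parent1, ev$frame - 1L) +
                   len_at(ev$parent2, ev$frame - 1L), tolerance = 1e-12)
  }
  expect_gt(nrow(tr$fission_events) + nrow(tr$fusion_events), 0)
})

test_that("patch ground truth respects lifetime and geometry bounds", {
  cfg <- sim_config(seed = 12, patch_rate = 0.3, drp1_rate = 0.15)
  tr <- simulate_dynamics(cfg)
  p <- tr$patches
  expect_gt(nrow(p), 0)
  expect_true(all(p$offset >= p$onset + 1L))
  expect_true(all(p$start >= 0 & p$end <= cfg$axon_length))
  expect_true(all(p$end > p$start))
  expect_true(all(p$class %in% c("fission_associated", "mito_associated",
                                 "non_mito")))
})

test_that("patch-conditioned fission places every site inside a patch", {
  cfg <- sim_config(seed = 77, n_mito = 10, axon_length = 80,
                    patch_rate = 0.4, fission_prob_per_10min = 0.6,
                    fission_patch_bias = 1, frac_moving = 0,
                    frac_oscillating = 0, fusion_prob_per_10min = 0)
  tr <- simulate_dynamics(cfg)
  expect_gt(nrow(tr$fission_events), 0)
  expect_equal(colocalization_fraction(tr$fission_events, tr$patches), 1.0)
})
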
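test_that("a constant single-interval track produces no events", {
  cfg <- noise_free(n_frames = 40, seed = 1)
  res <- analyze_truth(scripted_single(cfg), cfg)
  expect_equal(nrow(res$fission), 0)
  expect_equal(nrow(res$fusion), 0)
})

test_that("a scripted fission is called at the right frame and position", {
  cfg <- noise_free(n_frames = 60, seed = 1)
  truth <- scripted_fission(cfg, at = 40L, sep = 0.9)
  res <- analyze_truth(truth, cfg)
  expect_equal(nrow(res$fission), 1)
  expect_lte(abs(res$fission$frame - 40), 1)
  expect_lt(abs(res$fission$position - truth$fission_events$position), 0.3)
  expect_gt(res$fission$separation, 0.6)
})

test_that("constrictions that re-widen are never called as fission", {
  cfg <- noise_free(n_frames = 60, seed = 1)
  res <- analyze_truth(scripted_constriction(cfg, depth = 0.6), cfg)
  expect_equal(nrow(res$fission), 0)
  # even a deep constriction without separation stays uncalled
  res2 <- analyze_truth(scripted_constriction(cfg, depth = 0.97), cfg)
  expect_equal(nrow(res2$fission), 0)
})

test_that("fission is never called below the 0.6 um separation", {
  cfg <- noise_free(n_frames = 60, seed = 1)
  truth <- scripted_fission(cfg, at = 40L, sep = 0.5)  # under threshold
  res <- analyze_truth(truth, cfg)
  expect_equal(nrow(res$fission), 0)
})

test_that("fusion requires intensity mixing, additivity and redistribution", {
  cfg <- noise_free(n_frames = 60, seed = 1)
  frames <- seq_len(cfg$n_frames) - 1L
  approach <- pmax(24 - 0.9 * frames, 20.1)  # moving partner stops adjacent
  # touch without mixing: both keep their own intensity, never merge
  touch <- axon_truth(cfg, rbind(
    data.frame(frame = frames, track = 1L, start = 17, end = 20,
               intensity = 100),
    data.frame(frame = frames, track = 2L, start = approach,
               end = approach + 2, intensity = 200)))
  res <- analyze_truth(touch, cfg)
  expect_equal(nrow(res$fusion), 0)

  # true fusion: uniform additive product with redistributed intensity
  at <- min(which(approach <= 20.1)) - 1L
  fuse <- axon_truth(cfg, rbind(
    data.frame(frame = frames[frames < at], track = 1L, start = 17,
               end = 20, intensity = 100),
    data.frame(frame = frames[frames < at], track = 2L,
               start = approach[frames < at],
               end = approach[frames < at] + 2, intensity = 200),
    data.frame(frame = frames[frames >= at], track = 3L, start = 17,
               end = 22, intensity = 140)),
    fusion_events = data.frame(frame = at, position = 20, parent1 = 1L,
                               parent2 = 2L, child = 3L))
  res2 <- analyze_truth(fuse, cfg)
  expect_equal(nrow(res2$fusion), 1)
  expect_lte(abs(res2$fusion$frame - at), 2)
  expect_lt(abs(res2$fusion$additivity_resid), 0.12)
  expect_gt(res2$fusion$redistribution_gain, 0)  # post CV < parent CV
})

test_that("event rate counts distinct parents scaled to 10 minutes", {
  ev <- data.frame(parent = c(1:20, 1:5))  # 5 repeat fissions
  expect_equal(event_rate(ev, 100, 600), 20)
  expect_equal(event_rate(ev[0, ], 100, 600), 0)
  expect_equal(event_rate(ev, 100, 300), 40)  # scaled to 10 min
  expect_equal(event_rate(ev, 100, 600, cohort = 1:10), 10)
  expect_error(event_rate(ev, 0, 600), "n_mitochondria")
})

test_that("post-fission transport follows the > 1 um excursion rule", {
  ev <- data.frame(frame = 5L, child1 = 1L, child2 = 2L)
  still <- data.frame(frame = rep(0:29, 2), track = rep(1:2, each = 30),
                      start = rep(c(10, 20), each = 30))
  still$end <- still$start + 2
  expect_equal(post_fission_transport(ev, still), 0)

  moving <- still
  moving$start[moving$track == 2] <- 20 + c(rep(0, 6), cumsum(rep(0.5, 24)))
  moving$end <- moving$start + 2
  expect_equal(post_fission_transport(ev, moving), 1)

  cfg <- sim_config(axon_length = 400, n_mito = 60, n_frames = 100,
                    frac_moving = 0, frac_oscillating = 0,
                    p_transport_after_fission = 1,
                    fission_prob_per_10min = 0.6, fusion_prob_per_10min = 0,
                    patch_rate = 0, drp1_rate = 0, seed = 44)
  tr <- simulate_dynamics(cfg)
  ok <- tr$fission_events$frame <= cfg$n_frames - 25
  expect_gt(sum(ok), 5)
  expect_equal(post_fission_transport(tr$fission_events[ok, ], tr$tracks), 1)
})
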
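test_that("patch detection finds scripted patches and rejects flickers", {
  cfg <- noise_free(n_frames = 40, seed = 1)
  frames <- seq_len(cfg$n_frames) - 1L
  truth <- axon_truth(cfg, data.frame(frame = frames, track = 1L,
                                      start = 10, end = 12, intensity = 100))
  truth$patches <- data.frame(
    patch = 1:3, channel = "actin",
    onset = c(5L, 20L, 33L), offset = c(12L, 26L, 33L),  # third: 1 frame
    start = c(11, 30, 45), end = c(11.8, 30.6, 45.5),
    class = "non_mito", overlaps_fission = FALSE, fate_filopodium = FALSE)
  ser <- extract_profiles(render_stack(truth, cfg)$actin,
                          pixel_size = cfg$pixel_size, frame_interval = 3,
                          channel = "actin")
  det <- detect_patches(ser)
  expect_equal(nrow(det), 2)  # single-frame flicker rejected
  det <- det[order(det$onset), ]
  expect_lte(max(abs(det$onset - c(5, 20))), 1)
  expect_lte(max(abs(det$offset - c(12, 26))), 1)
  expect_equal(det$duration_s, (det$offset - det$onset + 1) * 3)

  flat <- extract_profiles(array(10, dim = c(7, 100, 5)), pixel_size = 0.12,
                           frame_interval = 3, channel = "actin")
  expect_equal(nrow(detect_patches(flat)), 0)
})

test_that("patch classification follows the spatial overlap rules", {
  tracks <- data.frame(frame = rep(0:20, 1), track = 1L, start = 10,
                       end = 14)
  events <- data.frame(frame = 10L, position = 11)
  patches <- data.frame(patch = 1:3, channel = "actin",
                        onset = c(8L, 8L, 8L), offset = c(14L, 14L, 14L),
                        start = c(10.5, 13, 30), end = c(11.5, 13.8, 31))
  cl <- classify_patches(patches, tracks, events)
  expect_equal(cl$class,
               c("fission_associated", "mito_associated", "non_mito"))

  # ground-truth labels agree with the classifier at zero noise
  cfg <- sim_config(seed = 13, patch_rate = 0.3, fission_prob_per_10min = 0.5)
  tr <- simulate_dynamics(cfg)
  re <- classify_patches(tr$patches, tr$tracks, tr$fission_events)
  expect_equal(re$class, tr$patches$class)
})

test_that("patch fate statistics report proportions and Fisher tests", {
  all_fil <- data.frame(class = rep(c("fission_associated",
                                      "mito_associated", "non_mito"), 5),
                        fate_filopodium = TRUE)
  st <- patch_fate_stats(all_fil)
  expect_equal(st$proportions$proportion, rep(1, 3))

  even <- data.frame(class = rep(c("fission_associated", "mito_associated"),
                                 each = 20),
                     fate_filopodium = rep(c(TRUE, FALSE), 20))
  st2 <- patch_fate_stats(even)
  p <- st2$fisher$p_value[st2$fisher$class1 == "fission_associated" &
                            st2$fisher$class2 == "mito_associated"]
  expect_equal(p, 1.0)  # identical 10/20 tables
  expect_true(is.na(
    st2$proportions$proportion[st2$proportions$class == "non_mito"]))

  set.seed(7)
  rnd <- data.frame(class = rep("mito_associated", 200),
                    fate_filopodium = stats::runif(200) < 0.3)
  st3 <- patch_fate_stats(rnd)
  phat <- st3$proportions$proportion[
    st3$proportions$class == "mito_associated"]
  ci <- stats::qbinom(c(0.025, 0.975), 200, 0.3) / 200
  expect_gte(phat, ci[1])
  expect_lte(phat, ci[2])
})

test_that("Drp1 accumulations per mitochondrion normalize to 10 min", {
  tracks <- data.frame(frame = rep(0:99, 2), track = rep(1:2, each = 100),
                       start = rep(c(10, 30), each = 100))
  tracks$end <- tracks$start + 3
  none <- data.frame(patch = integer(), channel = character(),
                     onset = integer(), offset = integer(),
                     start = numeric(), end = numeric())
  expect_equal(drp1_accumulations_per_mito(none, tracks, window = 300), 0)

  one <- data.frame(patch = 1L, channel = "drp1", onset = 10L, offset = 14L,
                    start = 11, end = 11.5)
  # one punctum on one of two mitochondria in a 5 min window
  expect_equal(drp1_accumulations_per_mito(one, tracks, window = 300),
               0.5 * 2)

  # scripted mean of 2 puncta per mitochondrion per 10 min
  set.seed(12)
  n_mito <- 40
  tracks2 <- data.frame(frame = rep(0:199, n_mito),
                        track = rep(seq_len(n_mito), each = 200),
                        start = rep(seq(5, by = 8, length.out = n_mito),
                                    each = 200))
  tracks2$end <- tracks2$start + 3
  counts <- stats::rpois(n_mito, 2)
  pl <- list()
  for (i in seq_len(n_mito)) {
    if (counts[i] == 0) next
    for (k in seq_len(counts[i])) {
      pos <- stats::runif(1, tracks2$start[(i - 1) * 200 + 1] + 0.2,
                          tracks2$start[(i - 1) * 200 + 1] + 2.5)
      on <- sample(0:190, 1)
      pl[[length(pl) + 1]] <- data.frame(patch = length(pl) + 1L,
                                         channel = "drp1", onset = on,
                                         offset = on + 4L, start = pos,
                                         end = pos + 0.4)
    }
  }
  puncta <- do.call(rbind, pl)
  est <- drp1_accumulations_per_mito(puncta, tracks2, window = 600)
  lam_ci <- stats::qpois(c(0.025, 0.975), 2 * n_mito) / n_mito
  expect_gte(est, lam_ci[1])
  expect_lte(est, lam_ci[2])
})
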
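test_that("profile extraction reproduces raster values on flat input", {
  stk <- array(7, dim = c(7, 100, 3))
  ser <- extract_profiles(stk, pixel_size = 0.12, frame_interval = 3)
  expect_true(all(ser$profile == 7))
  # degenerate single-line transect equals the raster row
  stk[4, , 2] <- seq_len(100)
  ser1 <- extract_profiles(stk, pixel_size = 0.12, frame_interval = 3,
                           width = 0.12)
  expect_equal(ser1$profile[2, ], as.numeric(seq_len(100)))
})

test_that("a path leaving the image raises an error", {
  stk <- array(0, dim = c(7, 100, 2))
  bad <- axon_path(rbind(c(0, 0.4), c(30, 0.4)))  # 30 um > 12 um wide image
  expect_error(extract_profiles(stk, path = bad, pixel_size = 0.12,
                                frame_interval = 3), "exits")
})

test_that("segmentation recovers lengths and rejects background frames", {
  cfg <- noise_free(n_frames = 3, seed = 1)
  truth <- scripted_single(cfg, start = 20, len = 2)
  ser <- extract_profiles(render_stack(truth, cfg, channels = "mito")$mito,
                          pixel_size = 0.12, frame_interval = 3)
  seg <- segment_mitochondria(ser, 0)
  expect_equal(nrow(seg), 1)
  expect_lt(abs(seg$length - 2), 0.12)
  expect_lt(abs(seg$start - 20), 0.12)
  expect_error(segment_mitochondria(ser, 99), "out of range")

  flat <- extract_profiles(array(10, dim = c(7, 200, 2)), pixel_size = 0.12,
                           frame_interval = 3)
  expect_equal(nrow(segment_mitochondria(flat, 0)), 0)
})

test_that("doubled-plateau overlap is flagged and excluded from length", {
  cfg <- noise_free(n_frames = 2, seed = 1)
  truth <- scripted_single(cfg, start = 20, len = 2, intensity = 100)
  truth$tracks <- rbind(truth$tracks,
                        transform(truth$tracks, track = 2L))  # co-located
  ser <- extract_profiles(render_stack(truth, cfg, channels = "mito")$mito,
                          pixel_size = 0.12, frame_interval = 3)
  ref <- 100 * 0.48  # single-mitochondrion plateau after PSF spread
  seg <- segment_mitochondria(ser, 0, reference_plateau = ref)
  expect_equal(nrow(seg), 1)
  expect_true(seg$excluded_overlap)
  expect_true(is.na(mean_mito_length(seg)))
  expect_equal(as.numeric(measure_density(seg, 60)), 10 / 60)
})

test_that("linking follows stationary and well-separated mitochondria", {
  cfg <- noise_free(n_frames = 30, seed = 1)
  truth <- scripted_single(cfg, start = 10, len = 2)
  truth$tracks <- rbind(truth$tracks,
                        transform(truth$tracks, track = 2L,
                                  start = start + 20, end = end + 20))
  ser <- extract_profiles(render_stack(truth, cfg, channels = "mito")$mito,
                          pixel_size = 0.12, frame_interval = 3)
  linked <- link_tracks(segment_series(ser))
  expect_equal(length(unique(linked$tracks$track)), 2)
  expect_equal(as.integer(table(linked$tracks$track)), c(30L, 30L))
  expect_equal(nrow(linked$candidates), 0)
})

test_that("a scripted fission yields exactly one split candidate", {
  cfg <- noise_free(n_frames = 60, seed = 1)
  truth <- scripted_fission(cfg, at = 40L)
  ser <- extract_profiles(render_stack(truth, cfg, channels = "mito")$mito,
                          pixel_size = 0.12, frame_interval = 3)
  linked <- link_tracks(segment_series(ser))
  splits <- linked$candidates[linked$candidates$kind == "split", ]
  expect_equal(nrow(splits), 1)
  expect_equal(splits$frame, 40L)
})

test_that("density and mass follow their definitions", {
  five <- data.frame(frame = 0, start = 1:5, end = 1:5 + 0.5,
                     length = 0.5, intensity = 1, excluded_overlap = FALSE)
  expect_equal(as.numeric(measure_density(five, 25)), 2.0)
  expect_equal(as.numeric(measure_density(five[0, ], 25)), 0.0)
  expect_error(measure_density(five, 0), "sampled_length")
  expect_equal(mito_mass(2.0, 1.0), 2.0)
  expect_equal(mito_mass(3.1, 0), 0)
})

test_that("density is invariant to pixel size at fixed physical content", {
  for (ps in c(0.12, 0.06)) {
    cfg <- noise_free(n_frames = 2, pixel_size = ps, n_mito = 6, seed = 8,
                      fission_prob_per_10min = 0, patch_rate = 0,
                      drp1_rate = 0)
    tr <- simulate_dynamics(cfg)
    ser <- extract_profiles(render_stack(tr, cfg, channels = "mito")$mito,
                            pixel_size = ps, frame_interval = 3)
    seg <- segment_mitochondria(ser, 0)
    dens <- as.numeric(measure_density(seg, cfg$axon_length))
    if (ps == 0.12) dens_coarse <- dens else {
      expect_equal(dens, dens_coarse)
    }
  }
})

test_that("the distal sampling window applies the growth-cone rules", {
  p <- axon_path(rbind(c(0, 0), c(100, 0)), growth_cone_boundary = 90)
  expect_equal(distal_sampling_window(p), c(40, 90))
  p2 <- axon_path(rbind(c(0, 0), c(100, 0)))
  expect_equal(distal_sampling_window(p2), c(40, 90))  # 10 um fallback
  p3 <- axon_path(rbind(c(0, 0), c(55, 0)), growth_cone_boundary = 50)
  expect_error(distal_sampling_window(p3), "too short")
})

test_that("branch classification uses the strict 10 um rule", {
  b <- branch_density(c(5, 12, 30), 100)
  expect_equal(b$n_branches, 2)
  expect_equal(b$per_100um, 2.0)
  expect_equal(branch_density(10.0, 50)$n_branches, 0)
  expect_equal(branch_density(numeric(0), 80)$per_100um, 0.0)
  expect_error(branch_density(c(1), 0), "axon_length")
})
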
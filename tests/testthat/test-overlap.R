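test_that("the reference 20-event dataset reproduces its published summary", {
  tab <- reference_overlap_table()
  expect_equal(nrow(tab), 20)
  s <- summary(tab)
  expect_equal(round(s$mean[s$quantity == "mito_length_A"], 1), 8.3)
  expect_equal(round(s$sem[s$quantity == "mito_length_A"], 1), 0.8)
  expect_equal(round(s$mean[s$quantity == "patch_length_B"], 2), 0.83)
  expect_equal(round(s$sem[s$quantity == "patch_length_B"], 2), 0.16)
})

test_that("the random-overlap product matches in both dialects", {
  tab <- reference_overlap_table()
  p <- random_overlap_probability(tab)
  # rounded-proportion (table) dialect reproduces the published value
  expect_equal(p$p_table, 1.75e-21, tolerance = 0.005)
  # full precision differs from the table dialect
  expect_equal(p$p_full, 2.34e-21, tolerance = 0.005)
  expect_gt(p$p_full / p$p_table, 1.2)
})

test_that("proportions round to the two-decimal table dialect", {
  t1 <- overlap_table(8.15, 0.69)
  expect_equal(t1$C_table, 0.08)
  t2 <- overlap_table(5, 5)  # full coverage
  expect_equal(t2$C, 1.0)
  expect_equal(random_overlap_probability(t2)$p_full, 1.0)
  expect_error(overlap_table(5, 6), "exceeds")
  expect_error(overlap_table(c(5, 0), c(1, 0)), "lengths must be > 0")
  suppressWarnings(
    expect_warning(p0 <- random_overlap_probability(overlap_table(5, 0)),
                   "zero"))
  expect_equal(p0$p_full, 0)
  expect_equal(p0$p_table, 0)
})

test_that("log-domain accumulation equals the direct product", {
  set.seed(3)
  for (i in 1:20) {
    C <- stats::runif(sample(3:25, 1), 0.01, 1)
    tab <- overlap_table(rep(10, length(C)), 10 * C)
    p <- random_overlap_probability(tab)
    expect_equal(p$p_full, prod(tab$C), tolerance = 1e-12)
    expect_equal(p$p_table, prod(tab$C_table), tolerance = 1e-12)
  }
})

test_that("each row's C equals the Monte-Carlo random-overlap probability", {
  set.seed(42)
  A <- 10
  patches <- rbind(c(1.0, 1.8), c(4.2, 4.9), c(7.5, 8.6))
  B <- sum(patches[, 2] - patches[, 1])
  C <- overlap_table(A, B)$C
  draws <- stats::runif(1e5, 0, A)
  inside <- vapply(draws, function(x) {
    any(x >= patches[, 1] & x < patches[, 2])
  }, logical(1))
  mc <- mean(inside)
  se <- sqrt(C * (1 - C) / 1e5)
  expect_lt(abs(mc - C), 4 * se)
})

test_that("colocalization fraction reproduces printed-count arithmetic", {
  # 25 fission sites, 20 inside patches
  ev <- data.frame(frame = 1:25, position = c(seq(1, 20) + 0.5, 100:104))
  patches <- data.frame(onset = 0L, offset = 30L,
                        start = seq(1, 20), end = seq(1, 20) + 0.9)
  expect_equal(colocalization_fraction(ev, patches), 0.8)
  none <- data.frame(frame = 1:3, position = c(50, 60, 70))
  expect_equal(colocalization_fraction(none, patches), 0)
  expect_error(colocalization_fraction(ev[0, ], patches), "no fission")
})

test_that("overlap tables are built from events, patches and tracks", {
  tracks <- data.frame(frame = rep(0:10, 1), track = 1L, start = 10, end = 20)
  ev <- data.frame(frame = 5L, position = 13, parent = 1L)
  patches <- data.frame(patch = 1:2, channel = "actin", onset = 0L,
                        offset = 10L, start = c(12, 19.5), end = c(13, 21))
  tab <- build_overlap_table(ev, patches, tracks)
  expect_equal(tab$A, 10)
  expect_equal(tab$B, 1.5)  # second patch clipped at the mitochondrion end
  expect_equal(tab$C, 0.15)
})

test_that("null-simulation colocalization calibrates the statistic", {
  hits <- 0; nev <- 0; cs <- c()
  for (s in 1:25) {
    cfg <- sim_config(seed = s + 300, n_mito = 10, axon_length = 80,
                      patch_rate = 0.25, drp1_rate = 0,
                      fission_prob_per_10min = 0.5,
                      fusion_prob_per_10min = 0, frac_moving = 0,
                      frac_oscillating = 0, fission_patch_bias = 0)
    tr <- simulate_dynamics(cfg)
    if (!nrow(tr$fission_events)) next
    tab <- build_overlap_table(tr$fission_events, tr$patches, tr$tracks)
    cs <- c(cs, tab$C)
    hits <- hits + colocalization_fraction(tr$fission_events, tr$patches) *
      nrow(tr$fission_events)
    nev <- nev + nrow(tr$fission_events)
  }
  expect_gt(nev, 50)
  se <- sqrt(mean(cs) * (1 - mean(cs)) / nev)
  expect_lt(abs(hits / nev - mean(cs)), 3 * se + 0.01)
})
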
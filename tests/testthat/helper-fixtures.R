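# Shared fixture builders. Everything is generated in code; rendered
# fixtures are tiny (one axon, noise off) so tests stay fast.

# Scripted truth: one stationary mitochondrion over n frames.
scripted_single <- function(config, start = 10, len = 2, intensity = 100) {
  frames <- seq_len(config$n_frames) - 1L
  axon_truth(config, data.frame(frame = frames, track = 1L, start = start,
                                end = start + len, intensity = intensity))
}

# Scripted truth: parent splits at `at` with an instantaneous separation.
scripted_fission <- function(config, at = 40L, start = 10, len = 3,
                             split_frac = 0.4, sep = 0.9,
                             intensity = 100) {
  frames <- seq_len(config$n_frames) - 1L
  pos <- start + split_frac * len
  pre <- frames[frames < at]
  post <- frames[frames >= at]
  tracks <- rbind(
    data.frame(frame = pre, track = 1L, start = start, end = start + len,
               intensity = intensity),
    data.frame(frame = post, track = 2L, start = start - sep / 2,
               end = pos - sep / 2, intensity = intensity),
    data.frame(frame = post, track = 3L, start = pos + sep / 2,
               end = start + len + sep / 2, intensity = intensity))
  axon_truth(config, tracks,
             fission_events = data.frame(frame = at, position = pos,
                                         parent = 1L, child1 = 2L,
                                         child2 = 3L,
                                         transport_follows = FALSE))
}

# Scripted truth: a constriction that dims but re-widens, never separating.
scripted_constriction <- function(config, from = 35L, to = 45L,
                                  depth = 0.6) {
  truth <- scripted_single(config, start = 10, len = 3)
  truth$constrictions <- data.frame(track = 1L, frame_on = from,
                                    frame_off = to, position = 11.2,
                                    depth = depth)
  truth
}

# Render one channel noise-free and run the core mitochondria analysis.
analyze_truth <- function(truth, config, params = list()) {
  stk <- render_stack(truth, config, channels = "mito")
  analyze_axon(stk, pixel_size = config$pixel_size,
               frame_interval = config$frame_interval, params = params)
}

noise_free <- function(...) {
  sim_config(noise_gain = 0, noise_sd = 0, ...)
}

# Study-condition configs for noise-free oracle fixtures: fission axons
# (fusion disabled) and fusion axons (contact always fuses).
fission_fixture_config <- function(seed) {
  noise_free(seed = seed, fusion_prob_per_10min = 0, patch_rate = 0,
             drp1_rate = 0)
}
fusion_fixture_config <- function(seed) {
  noise_free(seed = seed, fission_prob_per_10min = 0,
             fusion_prob_per_10min = 1, frac_moving = 0.5,
             frac_oscillating = 0, patch_rate = 0, drp1_rate = 0)
}

# A simple position trace as a one-track data.frame (centre positions given;
# fixed length so leading/trailing ends move rigidly).
trace_track <- function(positions, len = 2) {
  data.frame(frame = seq_along(positions) - 1L, start = positions,
             end = positions + len)
}

# Independent brute-force run decomposition: scan the signed step sequence
# directly for pauses of >= 6 s and count sign changes. Kept deliberately
# naive (nested loops) so it shares no code with extract_runs().
oracle_runs <- function(track, frame_interval = 3) {
  track <- track[order(track$frame), ]
  ctr <- (track$start + track$end) / 2
  d_ctr <- diff(ctr)
  step <- ifelse(d_ctr >= 0, diff(track$end), diff(track$start))
  moving <- abs(step) > 0.24
  n <- length(step)
  pause_len <- ceiling(6 / frame_interval)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (!moving[i]) { i <- i + 1; next }
    j <- i
    last_move <- i
    while (j < n) {
      # extend while the next non-movement stretch is shorter than a pause
      k <- j + 1
      while (k <= n && !moving[k]) k <- k + 1
      if (k > n) break
      if (k - j - 1 >= pause_len) break
      j <- k
      last_move <- k
    }
    span <- i:last_move
    sgn <- sign(step[span][moving[span]])
    switches <- 0
    if (length(sgn) > 1) {
      for (q in 2:length(sgn)) if (sgn[q] != sgn[q - 1]) switches <- switches + 1
    }
    runs[[length(runs) + 1]] <- data.frame(
      start_frame = track$frame[i], end_frame = track$frame[last_move + 1],
      run_length = sum(abs(step[span])),
      net_displacement = sum(step[span]),
      n_switches = switches)
    i <- last_move + 1
  }
  if (length(runs)) do.call(rbind, runs) else
    data.frame(start_frame = integer(), end_frame = integer(),
               run_length = numeric(), net_displacement = numeric(),
               n_switches = integer())
}

# Random run-and-pause trace for the oracle-equivalence property.
random_trace <- function(n_steps = 60) {
  steps <- numeric(n_steps)
  i <- 1
  while (i <= n_steps) {
    if (stats::runif(1) < 0.4) {      # pause block
      k <- sample(1:4, 1)
      i <- i + k
    } else {                          # movement block
      k <- sample(1:6, 1)
      v <- stats::runif(1, 0.3, 1.5) * sample(c(-1, 1), 1)
      for (j in seq_len(k)) {
        if (i > n_steps) break
        steps[i] <- v * stats::runif(1, 0.8, 1.2)
        i <- i + 1
      }
    }
  }
  trace_track(10 + cumsum(c(0, steps)))
}
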
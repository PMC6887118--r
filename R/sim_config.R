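#' Simulation configuration for the synthetic axon timelapse generator
#'
#' Builds and validates the parameter set for [simulate_dynamics()] and
#' [render_stack()]. The defaults emulate the imaging conditions of chick
#' sensory axon timelapse recordings (110 frames at 3 s intervals,
#' 0.12 um/pixel) with mitochondria undergoing stochastic fission, fusion and
#' run-and-pause bidirectional transport, plus transient actin patches and
#' Drp1 puncta. Event probabilities are expressed per 10 min to match the
#' reporting unit of fission/fusion rates (% mitochondria per 10 min).
#'
#' @param axon_length axon length in um.
#' @param n_frames number of frames.
#' @param frame_interval interframe interval in seconds.
#' @param pixel_size pixel size in um.
#' @param n_mito number of mitochondria placed at frame 0.
#' @param mito_length_median,mito_length_shape log-normal length distribution
#'   (median in um, log-sd shape).
#' @param mito_intensity_range per-mitochondrion uniform plateau intensity
#'   range (arbitrary counts), mimicking the variable labeling of DsRed-mito.
#' @param fission_prob_per_10min probability that a mitochondrion undergoes
#'   fission within a 10 min window.
#' @param fusion_prob_per_10min probability that a contact-capable pair fuses
#'   within a 10 min window of sustained contact.
#' @param p_transport_after_fission probability that transport follows a
#'   fission event (one or, less often, both emergent mitochondria).
#' @param frac_moving,frac_oscillating initial motility class fractions; the
#'   remainder is stalled.
#' @param velocity_range transport velocity range in um/s.
#' @param pause_mean_s mean pause duration in s (pauses are at least 6 s so
#'   every scripted pause terminates a run under the measurement rule).
#' @param run_mean_s mean run bout duration in s.
#' @param run_switch_prob probability that a run contains a direction switch.
#' @param post_fission_drift_v,post_fission_drift_frames symmetric separation
#'   drift applied to both fission children (um/s, frames); the default gives
#'   a 0.9 um gap after two frames, past the 0.6 um completion criterion,
#'   while displacing each child by only 0.45 um (below the 1 um transport
#'   threshold).
#' @param fission_patch_bias probability that a fission site is placed inside
#'   an actin patch overlapping the mitochondrion (0 = site uniform on the
#'   mitochondrion, the null needed by the random-overlap statistic).
#' @param patch_rate actin patch formation rate, patches/um/min.
#' @param patch_duration_mean_s mean patch lifetime in s (minimum 2 frames).
#' @param patch_length_median,patch_length_shape log-normal patch extent (um).
#' @param drp1_rate Drp1 accumulation rate, puncta/um/min.
#' @param patch_intensity peak intensity of rendered patches/puncta.
#' @param fate_prob_filopodium named probabilities that a patch of each class
#'   (fission_associated, mito_associated, non_mito) gives rise to a
#'   filopodium; used only to stamp ground-truth fate flags.
#' @param psf_sigma Gaussian PSF sigma in um.
#' @param background background level in counts.
#' @param noise_gain,noise_sd Poisson gain (counts/photon; 0 disables shot
#'   noise) and Gaussian read-noise sd (0 disables).
#' @param seed integer seed; all stochastic draws in [simulate_dynamics()]
#'   come from one stream seeded with it (the renderer uses seed + 1).
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(axon_length = 60,
                       n_frames = 110,
                       frame_interval = 3,
                       pixel_size = 0.12,
                       n_mito = 8,
                       mito_length_median = 2.0,
                       mito_length_shape = 0.35,
                       mito_intensity_range = c(80, 120),
                       fission_prob_per_10min = 0.3,
                       fusion_prob_per_10min = 0.05,
                       p_transport_after_fission = 0.8,
                       frac_moving = 0.15,
                       frac_oscillating = 0.15,
                       velocity_range = c(0.1, 0.6),
                       pause_mean_s = 12,
                       run_mean_s = 15,
                       run_switch_prob = 0.55,
                       post_fission_drift_v = 0.075,
                       post_fission_drift_frames = 2,
                       fission_patch_bias = 0,
                       patch_rate = 0.25,
                       patch_duration_mean_s = 30,
                       patch_length_median = 0.6,
                       patch_length_shape = 0.4,
                       drp1_rate = 0.1,
                       patch_intensity = 60,
                       fate_prob_filopodium = c(fission_associated = 0.1,
                                                mito_associated = 0.55,
                                                non_mito = 0.1),
                       psf_sigma = 0.1,
                       background = 10,
                       noise_gain = 2,
                       noise_sd = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$fission_prob_per_10min, cfg$fusion_prob_per_10min,
             cfg$p_transport_after_fission, cfg$frac_moving,
             cfg$frac_oscillating, cfg$run_switch_prob,
             cfg$fission_patch_bias, cfg$fate_prob_filopodium)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  if (cfg$axon_length <= 0) stop("axon_length must be > 0")
  if (cfg$n_frames < 2) stop("n_frames must be at least 2")
  if (cfg$frac_moving + cfg$frac_oscillating > 1) {
    stop("frac_moving + frac_oscillating must not exceed 1")
  }
  if (length(cfg$velocity_range) != 2 || diff(cfg$velocity_range) < 0) {
    stop("velocity_range must be (low, high)")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' Rendered stack width implied by a configuration
#' @param config a `sim_config`.
#' @return number of pixels along the axon.
#' @export
stack_width <- function(config) {
  as.integer(ceiling(config$axon_length / config$pixel_size))
}

# Per-frame hazard equivalent to a per-10-min event probability.
per_frame_hazard <- function(p_per_10min, frame_interval) {
  1 - (1 - p_per_10min)^(frame_interval / 600)
}
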
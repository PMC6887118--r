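#' Ground-truth container for a simulated (or scripted) axon timelapse
#'
#' Bundles per-frame true mitochondrial intervals with event logs and patch
#' records. Normally produced by [simulate_dynamics()]; tests and worked
#' examples may also script one directly, e.g. to stage a constriction that
#' never completes fission.
#'
#' @param config a [sim_config()].
#' @param tracks data.frame with columns `frame` (0-based), `track`, `start`,
#'   `end` (um, half-open interval), `intensity`.
#' @param fission_events,fusion_events,patches,constrictions,lineage optional
#'   data.frames; see Details.
#'
#' @details `fission_events` columns: `frame`, `position`, `parent`,
#'   `child1`, `child2`, `transport_follows`. `fusion_events`: `frame`,
#'   `position`, `parent1`, `parent2`, `child`. `patches`: `patch`,
#'   `channel` ("actin" or "drp1"), `onset`, `offset` (frames), `start`,
#'   `end` (um), `class`, `overlaps_fission`, `fate_filopodium`.
#'   `constrictions` (`track`, `frame_on`, `frame_off`, `position`, `depth`)
#'   are purely a rendering instruction: the renderer dims a narrow zone of
#'   the mitochondrion without any change to the true interval, emulating an
#'   apparent constriction that re-widens.
#'
#' At every fission the children's true lengths sum exactly to the parent's;
#' at every fusion the child's length is exactly the sum of the parents'.
#'
#' @return an object of class `axon_truth`.
#' @export
axon_truth <- function(config, tracks,
                       fission_events = NULL, fusion_events = NULL,
                       patches = NULL, constrictions = NULL,
                       lineage = NULL) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(all(c("frame", "track", "start", "end", "intensity") %in%
                  names(tracks)))
  if (nrow(tracks) && any(tracks$end <= tracks$start)) {
    stop("tracks must have end > start")
  }
  empty_fis <- data.frame(frame = integer(), position = numeric(),
                          parent = integer(), child1 = integer(),
                          child2 = integer(), transport_follows = logical())
  empty_fus <- data.frame(frame = integer(), position = numeric(),
                          parent1 = integer(), parent2 = integer(),
                          child = integer())
  empty_patch <- data.frame(patch = integer(), channel = character(),
                            onset = integer(), offset = integer(),
                            start = numeric(), end = numeric(),
                            class = character(), overlaps_fission = logical(),
                            fate_filopodium = logical())
  empty_con <- data.frame(track = integer(), frame_on = integer(),
                          frame_off = integer(), position = numeric(),
                          depth = numeric())
  structure(list(
    config = config,
    tracks = tracks,
    fission_events = if (is.null(fission_events)) empty_fis else fission_events,
    fusion_events = if (is.null(fusion_events)) empty_fus else fusion_events,
    patches = if (is.null(patches)) empty_patch else patches,
    constrictions = if (is.null(constrictions)) empty_con else constrictions,
    lineage = lineage
  ), class = "axon_truth")
}

#' Simulate axonal mitochondrial dynamics with exact ground truth
#'
#' Event-driven stochastic simulation in continuous 1D arc-length (the pixel
#' grid only enters at render time). Mitochondria are intensity-labeled
#' intervals that undergo fission (per-10-min hazard on stalled
#' mitochondria, matching the observation that moving mitochondria were not
#' seen to fission), fusion on sustained contact, and run-and-pause
#' bidirectional transport. Both fission children receive a brief symmetric
#' separation drift so that every true event becomes callable under the
#' 0.6 um separation criterion; with probability
#' `p_transport_after_fission`, transport (a run of > 1 um) additionally
#' follows the event. Transient actin patches and Drp1 puncta are laid down
#' independently of the mitochondria; setting `fission_patch_bias > 0`
#' biases fission sites into patches, which provides the alternative to the
#' null hypothesis tested by the random-overlap statistic.
#'
#' All randomness comes from one stream seeded with `config$seed`, so equal
#' configurations reproduce identical event logs.
#'
#' @param config a [sim_config()].
#' @return an [axon_truth()] object.
#' @export
simulate_dynamics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  dt <- cf$frame_interval
  L <- cf$axon_length
  n_fr <- cf$n_frames
  margin <- 0.5
  min_child <- 2 * cf$pixel_size
  contact_dist <- 0.15

  h_fis <- per_frame_hazard(cf$fission_prob_per_10min, dt)
  h_fus <- per_frame_hazard(cf$fusion_prob_per_10min, dt)
  # When fusion is disabled mitochondria are impenetrable: movers stop at a
  # resolvable standoff from neighbours instead of passing through or
  # dwelling in sub-resolution adjacency (which mimics fusion and which the
  # measurement rules cannot exclude). With fusion enabled, contact is
  # allowed and resolved by the fusion hazard.
  standoff <- if (h_fus > 0) NA_real_ else 0.7

  ## --- initial placement -------------------------------------------------
  lens <- stats::rlnorm(cf$n_mito, meanlog = log(cf$mito_length_median),
                        sdlog = cf$mito_length_shape)
  if (sum(lens) + 2 * margin > 0.9 * L) {
    stop("axon too short to place ", cf$n_mito,
         " non-overlapping mitochondria (total length ",
         round(sum(lens), 1), " um on ", L, " um)")
  }
  min_gap <- 0.7
  free <- L - 2 * margin - sum(lens) - (cf$n_mito + 1) * min_gap
  if (free < 0) {
    stop("axon too short to place ", cf$n_mito,
         " resolvably separated mitochondria")
  }
  gaps <- stats::runif(cf$n_mito + 1)
  gaps <- min_gap + gaps / sum(gaps) * free
  starts <- margin + cumsum(gaps)[seq_len(cf$n_mito)] +
    c(0, cumsum(lens))[seq_len(cf$n_mito)]

  cls0 <- sample(rep(c("moving", "oscillating", "stalled"),
                     times = c(round(cf$frac_moving * cf$n_mito),
                               round(cf$frac_oscillating * cf$n_mito),
                               cf$n_mito)))[seq_len(cf$n_mito)]

  ## --- patches (independent of dynamics: the statistic's null) -----------
  total_min <- n_fr * dt / 60
  gen_patches <- function(rate, channel) {
    n <- stats::rpois(1, rate * L * total_min)
    if (n == 0) {
      return(data.frame(patch = integer(), channel = character(),
                        onset = integer(), offset = integer(),
                        start = numeric(), end = numeric()))
    }
    onset <- sample.int(n_fr, n, replace = TRUE) - 1L
    dur_fr <- pmax(2L, as.integer(round(
      stats::rexp(n, 1 / cf$patch_duration_mean_s) / dt)))
    ext <- stats::rlnorm(n, log(cf$patch_length_median), cf$patch_length_shape)
    ctr <- stats::runif(n, 0, L)
    data.frame(patch = seq_len(n), channel = channel, onset = onset,
               offset = pmin(onset + dur_fr - 1L, n_fr - 1L),
               start = pmax(0, ctr - ext / 2), end = pmin(L, ctr + ext / 2))
  }
  patches <- rbind(gen_patches(cf$patch_rate, "actin"),
                   gen_patches(cf$drp1_rate, "drp1"))
  if (nrow(patches)) patches$patch <- seq_len(nrow(patches))
  actin <- patches[patches$channel == "actin", , drop = FALSE]

  ## --- live state --------------------------------------------------------
  st <- data.frame(
    id = seq_len(cf$n_mito), start = starts, len = lens,
    intens = stats::runif(cf$n_mito, cf$mito_intensity_range[1],
                          cf$mito_intensity_range[2]),
    cls = cls0, mode = "idle", dir = 0, vel = 0,
    frames_left = 0L, bout2 = 0L,
    drift_left = 0L, drift_dir = 0, will_move = FALSE,
    osc_amp = 0, osc_phase = 0L, sib = NA_integer_, drift_v = 0,
    fus_cool = 0L,
    stringsAsFactors = FALSE)
  st$osc_amp[st$cls == "oscillating"] <-
    stats::runif(sum(st$cls == "oscillating"), 0.3, 0.45)
  st$osc_phase[st$cls == "oscillating"] <-
    sample.int(4, sum(st$cls == "oscillating"), replace = TRUE) - 1L

  next_id <- cf$n_mito + 1L
  rec <- vector("list", n_fr)
  fis_log <- list()
  fus_log <- list()
  born <- stats::setNames(rep(0L, cf$n_mito), as.character(seq_len(cf$n_mito)))
  origin <- stats::setNames(rep("init", cf$n_mito),
                            as.character(seq_len(cf$n_mito)))

  schedule_run <- function(row) {
    row$cls <- "moving"
    row$mode <- "run"
    row$dir <- sample(c(-1, 1), 1)
    row$vel <- stats::runif(1, cf$velocity_range[1], cf$velocity_range[2])
    # total run duration is drawn once; a scheduled direction switch splits
    # it into two bouts, so run duration is independent of switching
    tot <- max(4L, as.integer(round(stats::rexp(1, 1 / cf$run_mean_s) / dt)))
    if (stats::runif(1) < cf$run_switch_prob) {
      choices <- seq(2L, tot - 2L)
      b1 <- if (length(choices) == 1L) choices else sample(choices, 1L)
      row$frames_left <- b1
      row$bout2 <- tot - b1
    } else {
      row$frames_left <- tot
      row$bout2 <- 0L
    }
    row
  }
  schedule_pause <- function(row) {
    row$mode <- "pause"
    row$dir <- 0
    row$frames_left <- max(2L, as.integer(round(
      (RUN_TERMINATING_PAUSE_S + stats::rexp(1, 1 / cf$pause_mean_s)) / dt)))
    row
  }

  for (f in seq_len(n_fr) - 1L) {
    rec[[f + 1L]] <- data.frame(frame = f, track = st$id, start = st$start,
                                end = st$start + st$len, intensity = st$intens)
    if (f == n_fr - 1L) break

    ## movement -----------------------------------------------------------
    active <- which(st$drift_left > 0L | st$cls != "stalled")
    for (i in active) {
      r <- st[i, ]
      drifting <- r$drift_left > 0L
      if (drifting) {
        r$start <- r$start + r$drift_dir * r$drift_v * dt
        r$drift_left <- r$drift_left - 1L
        if (r$drift_left == 0L && r$will_move) {
          # transport after fission: first run continues away from the
          # sibling and covers comfortably more than the 1 um threshold
          r <- schedule_run(r)
          r$dir <- r$drift_dir
          r$frames_left <- max(r$frames_left,
                               as.integer(ceiling(1.2 / (r$vel * dt))))
          r$will_move <- FALSE
        }
      } else if (r$cls == "moving") {
        if (r$mode == "run") {
          r$start <- r$start + r$dir * r$vel * dt
          r$frames_left <- r$frames_left - 1L
          if (r$frames_left == 0L) {
            if (r$bout2 > 0L) {         # direction switch within the run
              r$dir <- -r$dir
              r$vel <- stats::runif(1, cf$velocity_range[1],
                                    cf$velocity_range[2])
              r$frames_left <- r$bout2
              r$bout2 <- 0L
            } else {
              r <- schedule_pause(r)
            }
          }
        } else {                        # pause (or idle just after fusion)
          r$frames_left <- r$frames_left - 1L
          if (r$frames_left <= 0L) r <- schedule_run(r)
        }
      } else if (r$cls == "oscillating") {
        step <- switch(r$osc_phase %% 4L + 1L, r$osc_amp, 0, -r$osc_amp, 0)
        r$start <- r$start + step
        r$osc_phase <- r$osc_phase + 1L
      }
      lo <- margin
      hi <- L - margin - r$len
      others <- setdiff(seq_len(nrow(st)), i)
      if (length(others) && !drifting) {
        # impenetrable neighbours: movers never pass through or overlap.
        # Under fusion they may approach to contact distance (except
        # freshly fused products still remodeling, which repel at a
        # resolvable standoff); with fusion off everything repels.
        so_j <- if (is.na(standoff)) {
          ifelse(st$fus_cool[others] > 0L, 0.7, 0.10)
        } else {
          rep(standoff, length(others))
        }
        is_left <- st$start[others] + st$len[others] / 2 <
          st$start[i] + st$len[i] / 2
        if (any(is_left)) {
          lo <- max(lo, max(st$start[others][is_left] +
                              st$len[others][is_left] + so_j[is_left]))
        }
        if (any(!is_left)) {
          hi <- min(hi, min(st$start[others][!is_left] - so_j[!is_left]) -
                      r$len)
        }
      }
      if (lo > hi) {               # squeezed: stay put
        r$start <- st$start[i]
        if (r$cls == "moving" && r$mode == "run") r <- schedule_pause(r)
      } else if (r$start < lo || r$start > hi) {
        r$start <- min(max(r$start, lo), hi)
        if (r$cls == "moving" && r$mode == "run") r <- schedule_pause(r)
      }
      st[i, ] <- r
    }

    ## fission -------------------------------------------------------------
    # fission hazard applies to resolvable stalled mitochondria: one that is
    # spatially overlapped by a passing neighbour is deferred (overlapping
    # mitochondria are excluded from analysis, so the truth must not hide
    # events inside unresolvable clumps)
    overlapped <- rep(FALSE, nrow(st))
    if (nrow(st) > 1) {
      ord <- order(st$start)
      s <- st$start[ord]; e <- s + st$len[ord]
      ov <- e[-length(e)] > s[-1]   # adjacent pairs in sorted order
      overlapped[ord[-length(ord)]] <- ov
      overlapped[ord[-1]] <- overlapped[ord[-1]] | ov
    }
    eligible <- which(st$cls == "stalled" & st$mode == "idle" &
                        st$drift_left == 0L & !overlapped &
                        st$len >= 2 * min_child + 1e-9)
    if (length(eligible)) {
      fire_ids <- st$id[eligible[stats::runif(length(eligible)) < h_fis]]
      for (fid in fire_ids) {
        i <- match(fid, st$id)
        r <- st[i, ]
        # room to separate the daughters: gaps to the nearest neighbours
        # (or field margin); fission defers while the site is too crowded
        # for the daughters to draw resolvably apart (a constriction there
        # would not complete)
        others <- setdiff(seq_len(nrow(st)), i)
        oend <- st$start[others] + st$len[others]
        left_end <- if (any(oend <= r$start + 1e-9)) {
          max(oend[oend <= r$start + 1e-9])
        } else margin
        right_start <- if (any(st$start[others] >= r$start + r$len - 1e-9)) {
          min(st$start[others][st$start[others] >= r$start + r$len - 1e-9])
        } else L - margin
        gap_l <- r$start - left_end
        gap_r <- right_start - (r$start + r$len)
        if (gap_l + gap_r < 1.6) next
        room_l <- max(0, gap_l - 0.4)
        room_r <- max(0, gap_r - 0.4)
        sep_total <- min(0.9, room_l + room_r)
        d_l <- min(room_l, max(sep_total / 2, sep_total - room_r))
        d_r <- sep_total - d_l
        int_lo <- r$start + min_child
        int_hi <- r$start + r$len - min_child
        pos <- NA_real_
        if (cf$fission_patch_bias > 0 &&
            stats::runif(1) < cf$fission_patch_bias) {
          # patch-conditioned fission: the site must fall inside an actin
          # patch on the mitochondrion; with none present the event defers
          # (hazard retries on later frames)
          act <- actin[actin$onset <= f + 1L & actin$offset >= f + 1L, ,
                       drop = FALSE]
          ov_lo <- pmax(act$start, int_lo)
          ov_hi <- pmin(act$end, int_hi)
          keep <- which(ov_hi > ov_lo)
          if (!length(keep)) next
          w <- ov_hi[keep] - ov_lo[keep]
          k <- keep[sample.int(length(keep), 1, prob = w)]
          pos <- stats::runif(1, ov_lo[k], ov_hi[k])
        }
        if (is.na(pos)) pos <- stats::runif(1, int_lo, int_hi)

        transport_follows <- stats::runif(1) < cf$p_transport_after_fission
        both <- transport_follows && stats::runif(1) < 0.25
        # the emergent mitochondrion moves into free axon space: transport
        # goes to the daughter with the larger outward room
        which_child <- if (gap_l >= gap_r) 1L else 2L
        ids <- c(next_id, next_id + 1L)
        next_id <- next_id + 2L
        kids <- st[c(i, i), ]
        kids$id <- ids
        kids$start <- c(r$start, pos)
        kids$len <- c(pos - r$start, r$start + r$len - pos)
        kids$cls <- "stalled"
        kids$mode <- "idle"
        kids$dir <- 0; kids$vel <- 0
        kids$frames_left <- 0L; kids$bout2 <- 0L
        kids$drift_left <- cf$post_fission_drift_frames
        kids$drift_dir <- c(-1, 1)
        kids$drift_v <- c(d_l, d_r) /
          (cf$post_fission_drift_frames * dt)
        kids$sib <- rev(ids)
        kids$will_move <- if (both) c(TRUE, TRUE) else {
          transport_follows & (1:2 == which_child)
        }
        st <- rbind(st[-i, ], kids)
        born[as.character(ids)] <- f + 1L
        origin[as.character(ids)] <- paste0("split:", r$id)
        fis_log[[length(fis_log) + 1L]] <- data.frame(
          frame = f + 1L, position = pos, parent = r$id,
          child1 = ids[1], child2 = ids[2],
          transport_follows = transport_follows)
      }
    }

    ## fusion --------------------------------------------------------------
    if (h_fus > 0 && nrow(st) > 1) {
      ord <- order(st$start)
      for (k in seq_len(length(ord) - 1L)) {
        i <- ord[k]; j <- ord[k + 1L]
        if (is.na(st$id[i]) || is.na(st$id[j])) next
        if (st$fus_cool[i] > 0L || st$fus_cool[j] > 0L) next
        gap <- st$start[j] - (st$start[i] + st$len[i])
        if (gap <= contact_dist && stats::runif(1) < h_fus) {
          len_sum <- st$len[i] + st$len[j]
          # the fused product must stay resolvably clear of other
          # neighbours; shift it if needed, or push the partners apart and
          # defer when there is no room
          others <- setdiff(seq_len(nrow(st)), c(i, j))
          others <- others[!is.na(st$id[others])]
          oend <- st$start[others] + st$len[others]
          lo <- margin
          if (any(oend <= st$start[i] + 1e-9)) {
            lo <- max(lo, max(oend[oend <= st$start[i] + 1e-9]) + 0.4)
          }
          hi <- L - margin - len_sum
          far <- st$start[others] >= st$start[j] + st$len[j] - 1e-9
          if (any(far)) {
            hi <- min(hi, min(st$start[others][far]) - 0.4 - len_sum)
          }
          if (lo > hi) {               # squeezed: separate instead
            mover <- if (st$mode[i] == "run") i else j
            if (mover == i) {
              st$start[i] <- st$start[j] - 0.7 - st$len[i]
            } else {
              st$start[j] <- st$start[i] + st$len[i] + 0.7
            }
            st[mover, ] <- schedule_pause(st[mover, ])
            next
          }
          id <- next_id
          next_id <- next_id + 1L
          merged <- st[i, ]
          merged$id <- id
          merged$start <- min(max(st$start[i], lo), hi)
          merged$len <- len_sum
          merged$intens <- (st$intens[i] * st$len[i] +
                              st$intens[j] * st$len[j]) / merged$len
          merged$cls <- "stalled"; merged$mode <- "idle"
          merged$fus_cool <- 6L
          merged$dir <- 0; merged$vel <- 0
          merged$frames_left <- 0L; merged$bout2 <- 0L
          merged$drift_left <- 0L; merged$will_move <- FALSE
          born[as.character(id)] <- f + 1L
          origin[as.character(id)] <- paste0("merge:", st$id[i], ",", st$id[j])
          fus_log[[length(fus_log) + 1L]] <- data.frame(
            frame = f + 1L, position = merged$start + st$len[i],
            parent1 = st$id[i], parent2 = st$id[j], child = id)
          st$id[j] <- NA_integer_
          st[i, ] <- merged
        }
      }
      st <- st[!is.na(st$id), , drop = FALSE]
    }
    st$fus_cool <- pmax(st$fus_cool - 1L, 0L)
  }

  tracks <- do.call(rbind, rec)
  fis <- if (length(fis_log)) do.call(rbind, fis_log) else NULL
  fus <- if (length(fus_log)) do.call(rbind, fus_log) else NULL

  lineage <- data.frame(track = as.integer(names(born)),
                        birth = unname(born),
                        origin = unname(origin))
  lineage$death <- vapply(lineage$track, function(id) {
    max(tracks$frame[tracks$track == id], -1L)
  }, integer(1))

  truth <- axon_truth(config, tracks, fission_events = fis,
                      fusion_events = fus, lineage = lineage)
  truth$patches <- stamp_patch_truth(patches, tracks, truth$fission_events, cf)
  truth
}

# Assign ground-truth class, fission-overlap flag, and filopodial fate to
# pre-generated patches (the same overlap rules the analysis applies, but on
# exact intervals).
stamp_patch_truth <- function(patches, tracks, fission_events, cf) {
  n <- nrow(patches)
  if (!n) {
    patches$class <- character(0)
    patches$overlaps_fission <- logical(0)
    patches$fate_filopodium <- logical(0)
    return(patches)
  }
  cls <- character(n)
  for (i in seq_len(n)) {
    p <- patches[i, ]
    fis_hit <- nrow(fission_events) && any(
      fission_events$frame >= p$onset - 1L &
        fission_events$frame <= p$offset + 1L &
        fission_events$position >= p$start &
        fission_events$position < p$end)
    if (fis_hit) {
      cls[i] <- "fission_associated"
      next
    }
    tr <- tracks[tracks$frame >= p$onset & tracks$frame <= p$offset, ]
    mito_hit <- nrow(tr) && any(pmin(tr$end, p$end) > pmax(tr$start, p$start))
    cls[i] <- if (mito_hit) "mito_associated" else "non_mito"
  }
  patches$class <- cls
  patches$overlaps_fission <- cls == "fission_associated"
  patches$fate_filopodium <- stats::runif(n) < cf$fate_prob_filopodium[cls]
  patches
}
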
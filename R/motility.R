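#' Per-frame signed leading-end steps of a track
#'
#' The leading end is the end facing the direction of current motion (the
#' distal end at rest); each step is the displacement of that end between
#' consecutive frames. Steps with magnitude at most 0.24 um (2 pixels of
#' localization jitter) are not detectable movement.
#'
#' @param track data.frame with `frame`, `start`, `end` for one track,
#'   consecutive frames.
#' @return data.frame with `frame` (of the step's later frame), `step`
#'   (signed um, positive = anterograde), `moving` (logical).
#' @export
track_steps <- function(track) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (n < 2) {
    return(data.frame(frame = integer(), step = numeric(),
                      moving = logical()))
  }
  ctr <- (track$start + track$end) / 2
  d_ctr <- diff(ctr)
  step <- ifelse(d_ctr >= 0, diff(track$end), diff(track$start))
  data.frame(frame = track$frame[-1], step = step,
             moving = abs(step) > DETECTABLE_MOVEMENT_UM)
}

#' Classify the motility of a track
#'
#' Classes are applied with precedence transported > oscillating > stalled:
#' transported if the excursion of either end from its starting position
#' exceeds 1 um; oscillating if there are detectable antero-retrograde
#' bouts below 1 um in either direction without net displacement; stalled
#' otherwise (no detectable movement). Tracks observed for less than one
#' minute are unclassifiable.
#'
#' @param track data.frame with `frame`, `start`, `end`.
#' @param frame_interval seconds per frame.
#' @return list with `class` ("stalled", "oscillating", "transported" or
#'   "unclassifiable"), `max_excursion` (um), `steps`.
#' @export
classify_motility <- function(track, frame_interval = 3) {
  track <- track[order(track$frame), ]
  duration <- (nrow(track) - 1) * frame_interval
  st <- track_steps(track)
  if (duration < 60) {
    return(list(class = "unclassifiable", max_excursion = NA_real_,
                steps = st))
  }
  exc <- max(abs(track$start - track$start[1]),
             abs(track$end - track$end[1]))
  cls <- if (exc > TRANSPORT_THRESHOLD_UM) {
    "transported"
  } else if (any(st$moving)) {
    "oscillating"
  } else {
    "stalled"
  }
  list(class = cls, max_excursion = exc, steps = st)
}

#' Decompose a track's movement into runs
#'
#' A run is a continuous bout of movement terminated by a pause of at least
#' 6 s (no detectable movement). Run length is the summed distance traveled
#' regardless of direction, so it always bounds the absolute net
#' displacement; direction switches within a run are counted as sign
#' changes between successive detectable-movement steps.
#'
#' @param track data.frame with `frame`, `start`, `end`.
#' @param frame_interval seconds per frame.
#' @return data.frame of runs: `start_frame`, `end_frame`, `run_length`
#'   (um), `net_displacement` (um), `n_switches`, `duration_s`.
#' @export
extract_runs <- function(track, frame_interval = 3) {
  st <- track_steps(track)
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      run_length = numeric(), net_displacement = numeric(),
                      n_switches = integer(), duration_s = numeric())
  if (!nrow(st) || !any(st$moving)) return(empty)

  pause_steps <- ceiling(RUN_TERMINATING_PAUSE_S / frame_interval)
  # label each step: runs are separated by >= pause_steps consecutive
  # non-moving steps
  r <- rle(st$moving)
  breakers <- !r$values & r$lengths >= pause_steps
  grp <- rep(cumsum(breakers), r$lengths)  # increments after each long pause
  grp[rep(breakers, r$lengths)] <- NA      # the pauses themselves

  out <- list()
  for (g in unique(grp[!is.na(grp)])) {
    idx <- which(grp == g & !is.na(grp))
    # trim to first..last moving step
    mv <- idx[st$moving[idx]]
    if (!length(mv)) next
    span <- seq(min(mv), max(mv))
    steps <- st$step[span]
    signs <- sign(st$step[span][st$moving[span]])
    out[[length(out) + 1L]] <- data.frame(
      start_frame = st$frame[min(span)] - 1L,
      end_frame = st$frame[max(span)],
      run_length = sum(abs(steps)),
      net_displacement = sum(steps),
      n_switches = sum(diff(signs) != 0),
      duration_s = length(span) * frame_interval)
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Velocity of each unidirectional bout within runs
#'
#' A bout is a maximal block of consecutive detectable-movement steps in
#' one direction; its velocity is the leading-end displacement over the
#' elapsed time. Bouts of a single frame transition are the minimum
#' measurable (2 frames); zero-displacement bouts do not exist by
#' construction (below the detectable-movement threshold).
#'
#' @param track data.frame with `frame`, `start`, `end`.
#' @param frame_interval seconds per frame.
#' @return data.frame of bouts: `start_frame`, `end_frame`, `direction`
#'   (+1 anterograde / -1 retrograde), `displacement` (um), `velocity_um_s`.
#' @export
run_velocity <- function(track, frame_interval = 3) {
  st <- track_steps(track)
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      direction = numeric(), displacement = numeric(),
                      velocity_um_s = numeric())
  if (!nrow(st) || !any(st$moving)) return(empty)
  sgn <- ifelse(st$moving, sign(st$step), 0)
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0)
  out <- lapply(keep, function(k) {
    span <- starts[k]:ends[k]
    disp <- sum(st$step[span])
    data.frame(start_frame = st$frame[starts[k]] - 1L,
               end_frame = st$frame[ends[k]],
               direction = r$values[k], displacement = disp,
               velocity_um_s = abs(disp) / (length(span) * frame_interval))
  })
  do.call(rbind, out)
}

#' Percent of observed time spent moving
#'
#' @param track data.frame with `frame`, `start`, `end`.
#' @param direction "any", "anterograde" or "retrograde".
#' @return percentage of inter-frame steps with detectable movement in the
#'   requested direction.
#' @export
percent_time_moving <- function(track, direction = c("any", "anterograde",
                                                     "retrograde")) {
  direction <- match.arg(direction)
  st <- track_steps(track)
  if (!nrow(st)) return(NA_real_)
  sel <- switch(direction,
                any = st$moving,
                anterograde = st$moving & st$step > 0,
                retrograde = st$moving & st$step < 0)
  100 * mean(sel)
}

#' Fraction of runs with at least one direction switch
#'
#' @param runs run table from [extract_runs()] (possibly row-bound over
#'   tracks).
#' @return fraction in `[0, 1]`.
#' @export
switch_fraction <- function(runs) {
  if (is.null(runs) || NROW(runs) == 0) stop("no runs supplied")
  mean(runs$n_switches >= 1)
}
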
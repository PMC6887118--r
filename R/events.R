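#' Confirm fission events from candidate track splits
#'
#' A candidate 1-to-2 split from [link_tracks()] is confirmed as a completed
#' fission only when, at some frame within `search` frames of the split,
#' (a) the intensity in the gap between the two emergent mitochondria has
#' decreased to the background level (minimum gap intensity at most
#' background mean + 2 background sd, with a 1%-of-plateau floor so the
#' criterion is defined on noise-free data), and (b) their edge-to-edge
#' separation exceeds 0.6 um (5 pixels). The call frame is the first frame
#' meeting both. Additionally the parent must have had a stable length
#' (within 2 pixels frame-to-frame) over the frames preceding the split:
#' fission occurs along stalled mitochondria, and this rejects apparent
#' splits produced by one mitochondrion passing another. Transient
#' constrictions that never reach background or never separate beyond
#' 0.6 um are never confirmed.
#'
#' @param linked result of [link_tracks()].
#' @param series the mitochondria [extract_profiles()] series.
#' @param search frames to scan after the split for completion.
#' @return data.frame of event records: `kind`, `frame` (call frame),
#'   `position` (gap center, um), `parent`, `child1`, `child2`,
#'   `gap_intensity`, `separation`.
#' @export
detect_fission <- function(linked, series, search = 10L) {
  cands <- linked$candidates
  cands <- cands[cands$kind == "split", , drop = FALSE]
  out <- list()
  ps <- series$pixel_size
  for (i in seq_len(nrow(cands))) {
    cd <- cands[i, ]
    parent <- cd$parent1
    pm <- linked$meta[linked$meta$track == parent, ]
    # a track arising from an (unconfirmed) merge is two mitochondria, not
    # a fission substrate
    if (nrow(pm) && pm$origin == "merge") next
    ref_len <- parent_reference_length(linked$tracks, parent,
                                       cd$frame - 1L, ps)
    if (is.na(ref_len)) next
    # split additivity: the daughters' lengths must account for the parent
    c1 <- track_at(linked$tracks, cd$child1, cd$frame)
    c2 <- track_at(linked$tracks, cd$child2, cd$frame)
    if (is.null(c1) || is.null(c2)) next
    if (abs(c1$length + c2$length - ref_len) > 2.5 * ps) next
    pl <- track_at(linked$tracks, parent, cd$frame - 1L)
    rec <- scan_fission(linked$tracks, series, cd$child1, cd$child2,
                        cd$frame, search, pl$intensity)
    if (!is.null(rec)) {
      rec$parent <- parent
      out[[length(out) + 1L]] <- rec
    }
  }
  events <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), frame = integer(), position = numeric(),
               parent = integer(), child1 = integer(), child2 = integer(),
               gap_intensity = numeric(), separation = numeric())
  # hard invariant: no fission at separation <= 0.6 um
  stopifnot(all(events$separation > MIN_FISSION_SEPARATION_UM))
  events[, c("kind", "frame", "position", "parent", "child1", "child2",
             "gap_intensity", "separation")]
}

# Reference length of a credible fission parent: the median length over up
# to 4 frames before the split, requiring all but at most one frame (the
# last, which may already be inflated by the opening gap) to agree with it
# within 2 px. Fission occurs along stalled mitochondria of stable length;
# a "parent" whose length keeps changing is another mitochondrion passing.
parent_reference_length <- function(tracks, id, last_frame, ps,
                                    n_check = 3L, tol_px = 2) {
  fr <- seq(max(0L, last_frame - n_check), last_frame)
  seg <- tracks[tracks$track == id & tracks$frame %in% fr, , drop = FALSE]
  if (!nrow(seg)) return(NA_real_)
  len <- seg$length[order(seg$frame)]
  ref <- stats::median(len)
  n_ok <- sum(abs(len - ref) <= tol_px * ps)
  if (n_ok >= length(len) - 1L && n_ok >= 1L) ref else NA_real_
}

scan_fission <- function(tracks, series, c1, c2, from, search, parent_plateau) {
  bg <- series$background
  for (g in from:(from + search)) {
    a <- track_at(tracks, c1, g)
    b <- track_at(tracks, c2, g)
    if (is.null(a) || is.null(b)) return(NULL)
    if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
    sep <- b$start - a$end
    if (sep <= MIN_FISSION_SEPARATION_UM) next
    gap_int <- gap_min_intensity(series, g, a$end, b$start)
    sig <- max(bg$sd[g + 1L], 0.01 * parent_plateau)
    if (gap_int <= bg$mean[g + 1L] + 2 * sig) {
      return(data.frame(kind = "fission", frame = g,
                        position = (a$end + b$start) / 2,
                        child1 = c1, child2 = c2,
                        gap_intensity = gap_int, separation = sep))
    }
  }
  NULL
}

gap_min_intensity <- function(series, frame, lo, hi) {
  v <- series$profile[frame + 1L, ]
  inside <- series$positions > lo & series$positions < hi
  if (any(inside)) min(v[inside]) else {
    v[which.min(abs(series$positions - (lo + hi) / 2))]
  }
}

#' Confirm fusion events from candidate track merges
#'
#' A candidate 2-to-1 merge is confirmed as fusion when the merged
#' mitochondrion (a) has a uniform intensity profile (coefficient of
#' variation of the smoothed, background-subtracted interior below
#' `cv_tol`), (b) has a length additive of the two parents within
#' `add_tol_px` pixels, sustained over the following `persist` frames
#' (rejecting transient apparent merges as one mitochondrion passes
#' another), and (c) is not a re-closing constriction: merges whose parents
#' were born together by a split of a common track and never separated
#' beyond 0.6 um are rejected. When the parents differed in intensity the
#' redistribution of signal into the uniform product is recorded as
#' evidence (`redistribution_gain` = between-parent CV minus post-merge CV).
#'
#' @param linked result of [link_tracks()].
#' @param series the mitochondria series.
#' @param cv_tol post-merge along-profile CV tolerance (default 0.15).
#' @param add_tol_px length-additivity tolerance in pixels (default 2).
#' @param persist frames over which additivity must hold.
#' @return data.frame of event records: `kind`, `frame`, `position`,
#'   `parent1`, `parent2`, `child`, `cv_post`, `additivity_resid`,
#'   `redistribution_gain`.
#' @export
detect_fusion <- function(linked, series, cv_tol = 0.15, add_tol_px = 2,
                          persist = 3L) {
  cands <- linked$candidates
  cands <- cands[cands$kind == "merge", , drop = FALSE]
  ps <- series$pixel_size
  out <- list()
  for (i in seq_len(nrow(cands))) {
    cd <- cands[i, ]
    p1 <- track_at(linked$tracks, cd$parent1, cd$frame - 1L)
    p2 <- track_at(linked$tracks, cd$parent2, cd$frame - 1L)
    if (is.null(p1) || is.null(p2)) next
    if (reclosing_constriction(linked, cd$parent1, cd$parent2)) next

    target <- p1$length + p2$length
    ok <- TRUE
    for (g in cd$frame:(cd$frame + persist - 1L)) {
      ch <- track_at(linked$tracks, cd$child1, g)
      if (is.null(ch)) {
        if (g == cd$frame) ok <- FALSE
        break
      }
      if (abs(ch$length - target) > add_tol_px * ps) { ok <- FALSE; break }
    }
    if (!ok) next
    # call frame: where the product's length best matches the additive
    # target (the frame of first apparent contact can pass marginally while
    # the partners still overlap mid-approach)
    resid <- vapply(cd$frame:(cd$frame + 2L), function(g) {
      chg <- track_at(linked$tracks, cd$child1, g)
      if (is.null(chg)) Inf else abs(chg$length - target)
    }, numeric(1))
    call_frame <- (cd$frame:(cd$frame + 2L))[which.min(resid)]
    ch <- track_at(linked$tracks, cd$child1, call_frame)

    cv_post <- interior_cv(series, call_frame, ch$start, ch$end)
    if (!is.finite(cv_post) || cv_post >= cv_tol) next
    cv_pre <- stats::sd(c(p1$intensity, p2$intensity)) /
      mean(c(p1$intensity, p2$intensity))
    # junction: merged start plus the left parent's length (parents keep
    # their lengths through the merge and cannot pass one another, so the
    # pre-merge order is the order at fusion)
    left_len <- if (p1$start <= p2$start) p1$length else p2$length
    junction <- ch$start + left_len
    out[[length(out) + 1L]] <- data.frame(
      kind = "fusion", frame = call_frame, position = junction,
      parent1 = cd$parent1, parent2 = cd$parent2, child = cd$child1,
      cv_post = cv_post,
      additivity_resid = ch$length - target,
      redistribution_gain = cv_pre - cv_post)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), frame = integer(), position = numeric(),
               parent1 = integer(), parent2 = integer(), child = integer(),
               cv_post = numeric(), additivity_resid = numeric(),
               redistribution_gain = numeric())
}

# Parents that were born by the same split and never drew apart beyond the
# fission separation criterion are two halves of a constricting
# mitochondrion, not fusion partners.
reclosing_constriction <- function(linked, t1, t2) {
  m <- linked$meta
  m1 <- m[m$track == t1, ]; m2 <- m[m$track == t2, ]
  if (!nrow(m1) || !nrow(m2)) return(FALSE)
  if (m1$origin != "split" || m2$origin != "split") return(FALSE)
  if (m1$origin_tracks != m2$origin_tracks || m1$birth != m2$birth) {
    return(FALSE)
  }
  a <- linked$tracks[linked$tracks$track == t1, ]
  b <- linked$tracks[linked$tracks$track == t2, ]
  common <- intersect(a$frame, b$frame)
  sep <- vapply(common, function(f) {
    ia <- a[a$frame == f, ]; ib <- b[b$frame == f, ]
    max(ib$start - ia$end, ia$start - ib$end)
  }, numeric(1))
  all(sep <= MIN_FISSION_SEPARATION_UM)
}

# Smoothed interior CV of the background-subtracted profile over [lo, hi].
interior_cv <- function(series, frame, lo, hi, shrink_px = 3L) {
  ps <- series$pixel_size
  v <- series$profile[frame + 1L, ]
  bg <- series$background$mean[frame + 1L]
  inside <- series$positions >= lo + shrink_px * ps &
    series$positions <= hi - shrink_px * ps
  x <- v[inside] - bg
  if (length(x) < 3) return(NA_real_)
  x <- stats::filter(x, rep(1 / 3, 3), sides = 2)
  x <- x[!is.na(x)]
  stats::sd(x) / mean(x)
}

#' Fission/fusion rate as % of mitochondria per 10 min
#'
#' Distinct mitochondria participating as event parents, as a percentage of
#' the mitochondria present at window start, scaled to a 10 min window. A
#' mitochondrion fissioning twice counts once (both events remain in the
#' log).
#'
#' @param events event table with a `parent` (fission) or
#'   `parent1`/`parent2` (fusion) column.
#' @param n_mitochondria denominator: mitochondria present at window start.
#' @param window_duration observation window in seconds.
#' @param cohort optional vector of track ids defining the denominator
#'   population; parents outside it (e.g. later-generation children) are not
#'   counted.
#' @return percentage per 10 min.
#' @export
event_rate <- function(events, n_mitochondria, window_duration,
                       cohort = NULL) {
  if (n_mitochondria <= 0) stop("n_mitochondria must be > 0")
  if (window_duration <= 0) stop("window_duration must be > 0")
  parents <- unique(unlist(
    events[intersect(c("parent", "parent1", "parent2"), names(events))]))
  if (!is.null(cohort)) parents <- intersect(parents, cohort)
  100 * length(parents) / n_mitochondria * (600 / window_duration)
}

#' Fraction of fission events followed by transport of an emergent child
#'
#' A child counts as transported if it moves more than 1 um (maximum
#' excursion of either end from its birth position) within `horizon`
#' seconds of the event.
#'
#' @param events fission event table with `frame`, `child1`, `child2`.
#' @param tracks track table (`track`, `frame`, `start`, `end`) — either
#'   ground truth or linked tracks.
#' @param horizon horizon in seconds.
#' @param frame_interval seconds per frame.
#' @return fraction in `[0, 1]` (NA if no events).
#' @export
post_fission_transport <- function(events, tracks, horizon = 60,
                                   frame_interval = 3) {
  if (!nrow(events)) return(NA_real_)
  h_fr <- as.integer(round(horizon / frame_interval))
  moved <- function(id, f0) {
    tr <- tracks[tracks$track == id & tracks$frame >= f0 &
                   tracks$frame <= f0 + h_fr, , drop = FALSE]
    if (nrow(tr) < 2) return(FALSE)
    tr <- tr[order(tr$frame), ]
    max(abs(tr$start - tr$start[1]), abs(tr$end - tr$end[1])) >
      TRANSPORT_THRESHOLD_UM
  }
  hits <- vapply(seq_len(nrow(events)), function(i) {
    moved(events$child1[i], events$frame[i]) ||
      moved(events$child2[i], events$frame[i])
  }, logical(1))
  mean(hits)
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching within a frame and position tolerance;
#' returns precision and recall for validating event calling on fixtures.
#'
#' @param detected detected event table (`frame`, `position`).
#' @param truth ground-truth event table (`frame`, `position`).
#' @param frame_tol matching tolerance in frames (calls can lag the true
#'   event by the frames needed to satisfy the 0.6 um separation).
#' @param pos_tol matching tolerance in um.
#' @return list with `precision`, `recall`, `n_detected`, `n_truth`.
#' @export
match_events <- function(detected, truth, frame_tol = 5L, pos_tol = 1.0) {
  n_d <- nrow(detected); n_t <- nrow(truth)
  if (!n_d || !n_t) {
    return(list(precision = if (n_d) 0 else NA_real_,
                recall = if (n_t) 0 else NA_real_,
                n_detected = n_d, n_truth = n_t))
  }
  used <- rep(FALSE, n_t)
  hit <- 0L
  for (i in order(detected$frame)) {
    ok <- which(!used &
                  abs(truth$frame - detected$frame[i]) <= frame_tol &
                  abs(truth$position - detected$position[i]) <= pos_tol)
    if (length(ok)) {
      used[ok[1]] <- TRUE
      hit <- hit + 1L
    }
  }
  list(precision = hit / n_d, recall = hit / n_t,
       n_detected = n_d, n_truth = n_t)
}
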
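#' Link per-frame segments into tracks
#'
#' Frame-to-frame assignment by maximal interval overlap (ties broken by
#' smaller intensity difference); segments without overlap may still be
#' linked across a small gap (`max_jump`) to follow fast movers. Unmatched
#' segments open or close tracks. A new segment that overlaps an
#' already-matched previous segment is recorded as a candidate 1-to-2 split
#' (possible fission); an unmatched previous segment overlapping a matched
#' new segment as a candidate 2-to-1 merge (possible fusion). Candidates
#' rewire the track topology (parent closes, children open) and are passed
#' to [detect_fission()] / [detect_fusion()] for confirmation; linking
#' itself asserts nothing about events.
#'
#' @param segments segment table from [segment_series()].
#' @param max_jump maximum centroid jump (um) for overlap-free linking.
#' @return list with `tracks` (segment table plus `track`), `meta`
#'   (per-track `birth`, `death`, `origin`, `origin_tracks`) and
#'   `candidates` (`kind` split/merge, `frame`, parent and child tracks).
#' @export
link_tracks <- function(segments, max_jump = 2.0) {
  if (is.null(segments) || !nrow(segments)) {
    return(list(tracks = segments, meta = NULL,
                candidates = data.frame(kind = character(), frame = integer(),
                                        parent1 = integer(), parent2 = integer(),
                                        child1 = integer(), child2 = integer())))
  }
  segments <- segments[order(segments$frame, segments$start), ]
  rownames(segments) <- NULL
  segments$track <- NA_integer_
  frames <- sort(unique(segments$frame))
  next_id <- 1L
  meta <- list()
  cands <- list()

  open_track <- function(origin, origin_tracks, birth) {
    id <- next_id
    next_id <<- next_id + 1L
    meta[[as.character(id)]] <<- list(track = id, birth = birth,
                                      death = birth, origin = origin,
                                      origin_tracks = origin_tracks)
    id
  }

  f0 <- frames[1]
  idx0 <- which(segments$frame == f0)
  for (i in idx0) segments$track[i] <- open_track("init", "", f0)

  for (fi in seq_along(frames)[-1]) {
    f_prev <- frames[fi - 1L]
    f <- frames[fi]
    old <- which(segments$frame == f_prev)
    new <- which(segments$frame == f)
    contiguous <- (f == f_prev + 1L)

    if (!contiguous || !length(old)) {
      for (i in new) segments$track[i] <- open_track("init", "", f)
      next
    }

    ## score all old-new pairs
    pairs <- expand.grid(o = old, n = new)
    ov <- pmin(segments$end[pairs$o], segments$end[pairs$n]) -
      pmax(segments$start[pairs$o], segments$start[pairs$n])
    ctr_o <- (segments$start[pairs$o] + segments$end[pairs$o]) / 2
    ctr_n <- (segments$start[pairs$n] + segments$end[pairs$n]) / 2
    dist <- abs(ctr_o - ctr_n)
    ldiff <- abs(segments$length[pairs$o] - segments$length[pairs$n])
    # overlap pairs always outrank gap-jump pairs; within the overlap class
    # a length mismatch penalizes the score so a mover's new position does
    # not capture a differently-sized neighbour's track
    cls <- ifelse(ov > 0, 1L, ifelse(dist <= max_jump, 0L, NA))
    score <- ifelse(ov > 0, ov - 0.5 * ldiff, -dist)
    idiff <- abs(segments$intensity[pairs$o] - segments$intensity[pairs$n])
    keep <- which(!is.na(cls))
    ord <- keep[order(-cls[keep], -score[keep], idiff[keep])]

    matched_o <- integer(0)
    matched_n <- integer(0)
    match_of_o <- list()  # old row -> new row
    match_of_n <- list()
    for (k in ord) {
      o <- pairs$o[k]; n <- pairs$n[k]
      if (o %in% matched_o || n %in% matched_n) next
      matched_o <- c(matched_o, o)
      matched_n <- c(matched_n, n)
      match_of_o[[as.character(o)]] <- n
      match_of_n[[as.character(n)]] <- o
      segments$track[n] <- segments$track[o]
      meta[[as.character(segments$track[o])]]$death <- f
    }

    ## split candidates: leftover new overlapping a matched old
    leftover_n <- setdiff(new, matched_n)
    used_in_split <- integer(0)
    for (n in leftover_n) {
      ovl <- pmin(segments$end[old], segments$end[n]) -
        pmax(segments$start[old], segments$start[n])
      # near-overlap (a fast daughter can clear the parent footprint in one
      # frame); event confirmation filters false candidates
      cand_o <- old[ovl > -1.0 & old %in% matched_o]
      if (length(cand_o)) {
        o <- cand_o[which.max(ovl[match(cand_o, old)])]
        sib <- match_of_o[[as.character(o)]]
        parent <- segments$track[o]
        c1 <- open_track("split", as.character(parent), f)
        c2 <- open_track("split", as.character(parent), f)
        # parent closes at f_prev; sibling is rewired to a child id
        meta[[as.character(parent)]]$death <- f_prev
        segments$track[sib] <- c1
        segments$track[n] <- c2
        cands[[length(cands) + 1L]] <- data.frame(
          kind = "split", frame = f, parent1 = parent, parent2 = NA_integer_,
          child1 = c1, child2 = c2)
        matched_n <- c(matched_n, n)
        used_in_split <- c(used_in_split, sib)
      }
    }

    ## merge candidates: leftover old overlapping a matched new; process in
    ## decreasing overlap so the physically engulfed segment wins when a
    ## cluster has several leftovers
    leftover_o <- setdiff(old, matched_o)
    best_ov <- vapply(leftover_o, function(o) {
      ovl <- pmin(segments$end[o], segments$end[new]) -
        pmax(segments$start[o], segments$start[new])
      if (length(ovl)) max(ovl) else -Inf
    }, numeric(1))
    used_child <- integer(0)
    for (o in leftover_o[order(-best_ov)]) {
      ovl <- pmin(segments$end[o], segments$end[new]) -
        pmax(segments$start[o], segments$start[new])
      # near-overlap: a mover's final approach step can jump from a clear
      # gap straight into the fused product
      cand_n <- new[ovl > -2.0 & new %in% matched_n & !(new %in% leftover_n)]
      cand_n <- setdiff(cand_n, c(used_in_split, used_child))
      if (length(cand_n)) {
        n <- cand_n[which.max(ovl[match(cand_n, new)])]
        other <- match_of_n[[as.character(n)]]
        if (is.null(other)) next
        used_child <- c(used_child, n)
        p1 <- segments$track[o]
        p2_old <- segments$track[other]
        child <- open_track("merge", paste(p1, p2_old, sep = ","), f)
        meta[[as.character(p1)]]$death <- f_prev
        meta[[as.character(p2_old)]]$death <- f_prev
        segments$track[n] <- child
        cands[[length(cands) + 1L]] <- data.frame(
          kind = "merge", frame = f, parent1 = p2_old, parent2 = p1,
          child1 = child, child2 = NA_integer_)
        matched_o <- c(matched_o, o)
      }
    }

    ## births
    for (n in setdiff(new, matched_n)) {
      segments$track[n] <- open_track("init", "", f)
    }
  }

  meta_df <- do.call(rbind, lapply(meta, function(m) {
    data.frame(track = m$track, birth = m$birth, death = m$death,
               origin = m$origin, origin_tracks = m$origin_tracks)
  }))
  cand_df <- if (length(cands)) do.call(rbind, cands) else
    data.frame(kind = character(), frame = integer(), parent1 = integer(),
               parent2 = integer(), child1 = integer(), child2 = integer())
  # refresh deaths from the final assignment
  deaths <- tapply(segments$frame, segments$track, max)
  births <- tapply(segments$frame, segments$track, min)
  meta_df$death <- as.integer(deaths[as.character(meta_df$track)])
  meta_df$birth <- as.integer(births[as.character(meta_df$track)])
  meta_df <- meta_df[!is.na(meta_df$death), ]
  list(tracks = segments, meta = meta_df, candidates = cand_df)
}

# Interval of a track at a frame; NULL if absent.
track_at <- function(tracks, id, frame) {
  r <- tracks[tracks$track == id & tracks$frame == frame, , drop = FALSE]
  if (nrow(r)) r[1, ] else NULL
}
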
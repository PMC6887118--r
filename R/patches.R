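#' Detect transient patches (actin) or accumulations (Drp1) in a channel
#'
#' Transient local elevations above background + `k_sigma` sd lasting at
#' least 2 frames become patch records (Drp1 accumulations follow the same
#' dynamics as actin patches, so one detector serves both). Per-frame
#' supra-threshold intervals are linked across frames by spatial overlap;
#' the spatial extent reported is the interval at the patch's peak frame.
#'
#' @param series an [extract_profiles()] series for the patch channel.
#' @param channel label stored in the output ("actin" or "drp1").
#' @param k_sigma detection threshold in background sds.
#' @param min_frames minimum lifetime in frames (default 2; single-frame
#'   flickers are rejected).
#' @return data.frame of patch records: `patch`, `channel`, `onset`,
#'   `offset` (frames), `start`, `end`, `position` (um), `duration_s`.
#' @export
detect_patches <- function(series, channel = series$channel, k_sigma = 3,
                           min_frames = 2L) {
  segs <- segment_series(series, k_sigma = k_sigma, overlap_factor = Inf)
  empty <- data.frame(patch = integer(), channel = character(),
                      onset = integer(), offset = integer(),
                      start = numeric(), end = numeric(),
                      position = numeric(), duration_s = numeric())
  if (is.null(segs) || !nrow(segs)) return(empty)
  linked <- link_tracks(segs)
  tr <- linked$tracks
  out <- lapply(unique(tr$track), function(id) {
    s <- tr[tr$track == id, ]
    if (nrow(s) < min_frames) return(NULL)
    peak <- s[which.max(s$intensity), ]
    data.frame(patch = id, channel = channel,
               onset = min(s$frame), offset = max(s$frame),
               start = peak$start, end = peak$end,
               position = (peak$start + peak$end) / 2,
               duration_s = (max(s$frame) - min(s$frame) + 1L) *
                 series$frame_interval)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Classify patches by their relation to mitochondria and fission sites
#'
#' A patch is `fission_associated` if its extent covers a fission position
#' within the association window of the event's call frame;
#' otherwise `mito_associated` if its extent overlaps any mitochondrion
#' footprint during its lifetime; otherwise `non_mito`.
#'
#' @param patches patch table ([detect_patches()] or ground truth).
#' @param tracks mitochondrial track table (`track`, `frame`, `start`,
#'   `end`).
#' @param fission_events fission event table (`frame`, `position`).
#' @param window association window in seconds around the call frame
#'   (default one frame: patches present at the first frame where fission
#'   is evident).
#' @param frame_interval seconds per frame.
#' @return `patches` with a `class` column set.
#' @export
classify_patches <- function(patches, tracks, fission_events,
                             window = 3, frame_interval = 3) {
  w <- as.integer(round(window / frame_interval))
  cls <- character(nrow(patches))
  for (i in seq_len(nrow(patches))) {
    p <- patches[i, ]
    hit <- nrow(fission_events) && any(
      fission_events$frame >= p$onset - w &
        fission_events$frame <= p$offset + w &
        fission_events$position >= p$start &
        fission_events$position < p$end)
    if (hit) {
      cls[i] <- "fission_associated"
      next
    }
    tr <- tracks[tracks$frame >= p$onset & tracks$frame <= p$offset, ]
    mito <- nrow(tr) && any(pmin(tr$end, p$end) > pmax(tr$start, p$start))
    cls[i] <- if (mito) "mito_associated" else "non_mito"
  }
  patches$class <- cls
  patches
}

#' Filopodium probability per patch class with pairwise Fisher tests
#'
#' Fate flags (whether the patch gave rise to a filopodium) come from
#' annotation or simulation truth; filopodia are not detected from images.
#'
#' @param patches patch table with `class` and `fate_filopodium`.
#' @return list with `proportions` (per-class data.frame, NA when a class
#'   has no patches) and `fisher` (pairwise two-sided Fisher exact
#'   p-values).
#' @export
patch_fate_stats <- function(patches) {
  classes <- c("fission_associated", "mito_associated", "non_mito")
  tab <- lapply(classes, function(cl) {
    x <- patches$fate_filopodium[patches$class == cl]
    data.frame(class = cl, n = length(x), n_filopodium = sum(x),
               proportion = if (length(x)) mean(x) else NA_real_)
  })
  tab <- do.call(rbind, tab)
  prs <- utils::combn(classes, 2)
  fisher <- apply(prs, 2, function(pr) {
    a <- tab[tab$class == pr[1], ]
    b <- tab[tab$class == pr[2], ]
    if (a$n == 0 || b$n == 0) return(NA_real_)
    m <- matrix(c(a$n_filopodium, a$n - a$n_filopodium,
                  b$n_filopodium, b$n - b$n_filopodium), nrow = 2)
    stats::fisher.test(m)$p.value
  })
  list(proportions = tab,
       fisher = data.frame(class1 = prs[1, ], class2 = prs[2, ],
                           p_value = fisher))
}

#' Drp1 accumulations per mitochondrion, normalized to 10 min
#'
#' Counts Drp1 patch records whose extent overlaps each mitochondrial track
#' footprint during the window, averaged over mitochondria present at
#' window start and scaled to a 10 min window.
#'
#' @param patches Drp1 patch table.
#' @param tracks mitochondrial track table.
#' @param window window duration in seconds.
#' @param frame_interval seconds per frame.
#' @return mean accumulations per mitochondrion per 10 min.
#' @export
drp1_accumulations_per_mito <- function(patches, tracks, window = 600,
                                        frame_interval = 3) {
  ids <- unique(tracks$track[tracks$frame == min(tracks$frame)])
  if (!length(ids)) stop("no tracks present at window start")
  n_fr <- as.integer(round(window / frame_interval))
  patches <- patches[patches$channel == "drp1" & patches$onset < n_fr, ,
                     drop = FALSE]
  counts <- vapply(ids, function(id) {
    tr <- tracks[tracks$track == id & tracks$frame < n_fr, , drop = FALSE]
    if (!nrow(patches) || !nrow(tr)) return(0L)
    hit <- vapply(seq_len(nrow(patches)), function(i) {
      p <- patches[i, ]
      s <- tr[tr$frame >= p$onset & tr$frame <= p$offset, , drop = FALSE]
      nrow(s) && any(pmin(s$end, p$end) > pmax(s$start, p$start))
    }, logical(1))
    sum(hit)
  }, integer(1))
  mean(counts) * (600 / window)
}
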
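#' Overlap table for the random-overlap probability statistic
#'
#' One row per fission event: A, the length of the mitochondrion that
#' underwent fission; B, the summed length of all patches present along it
#' at the first frame where fission was evident (clipped to the
#' mitochondrion before summing); and the proportion C = B/A of the
#' mitochondrion occupied by patches. C is also stored rounded to two
#' decimals (`C_table`), the precision convention of the published data
#' table this statistic follows.
#'
#' @param A mitochondrion lengths, um.
#' @param B summed patch lengths, um (must satisfy B <= A).
#' @return data.frame of class `overlap_table` with columns `A`, `B`, `C`,
#'   `C_table`.
#' @export
overlap_table <- function(A, B) {
  stopifnot(length(A) == length(B))
  if (any(A <= 0)) stop("mitochondrion lengths must be > 0")
  if (any(B < 0)) stop("summed patch lengths must be >= 0")
  if (any(B > A + 1e-9)) {
    stop("summed patch length exceeds mitochondrion length; ",
         "clip patch extents to the mitochondrion before summing")
  }
  out <- data.frame(A = A, B = B, C = pmin(B / A, 1),
                    C_table = round(pmin(B / A, 1), 2))
  class(out) <- c("overlap_table", "data.frame")
  out
}

#' Summary (mean and SEM of A and B) of an overlap table
#' @param object an [overlap_table()].
#' @param ... unused.
#' @return data.frame with mean and SEM of each column.
#' @export
summary.overlap_table <- function(object, ...) {
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  data.frame(quantity = c("mito_length_A", "patch_length_B", "proportion_C"),
             mean = c(mean(object$A), mean(object$B), mean(object$C)),
             sem = c(sem(object$A), sem(object$B), sem(object$C)),
             n = nrow(object))
}

#' Build the overlap table from detected events and patches
#'
#' For each fission event, A is the parent mitochondrion's length at the
#' frame before the split became evident and B the summed length of patch
#' extents overlapping the parent interval among patches active at the
#' event frame.
#'
#' @param fission_events event table with `frame`, `parent`.
#' @param patches patch table with `onset`, `offset`, `start`, `end`.
#' @param tracks track table (`track`, `frame`, `start`, `end`), ground
#'   truth or linked.
#' @param channel patch channel to use.
#' @return an [overlap_table()]; events whose parent interval cannot be
#'   recovered are skipped.
#' @export
build_overlap_table <- function(fission_events, patches, tracks,
                                channel = "actin") {
  patches <- patches[patches$channel == channel, , drop = FALSE]
  A <- numeric(0); B <- numeric(0)
  for (i in seq_len(nrow(fission_events))) {
    ev <- fission_events[i, ]
    par <- tracks[tracks$track == ev$parent & tracks$frame < ev$frame, ,
                  drop = FALSE]
    if (!nrow(par)) next
    par <- par[which.max(par$frame), ]
    act <- patches[patches$onset <= ev$frame & patches$offset >= ev$frame, ,
                   drop = FALSE]
    ov <- pmax(pmin(act$end, par$end) - pmax(act$start, par$start), 0)
    A <- c(A, par$end - par$start)
    B <- c(B, min(sum(ov), par$end - par$start))
  }
  overlap_table(A, B)
}

#' Random-overlap probability of patches with all observed fission sites
#'
#' The probability that a fission site placed at random on its
#' mitochondrion would fall inside a patch is the per-event proportion C;
#' the probability of observing patch overlap at every one of the n
#' observed fission sites by chance is the product of the C values,
#' accumulated in log space to avoid underflow. Both the full-precision
#' product and the product of the two-decimal rounded proportions (the
#' published-table convention) are returned.
#'
#' @param table an [overlap_table()].
#' @return list with `p_full`, `p_table`, and `n` rows. Any C equal to 0
#'   (an observed overlap with zero coverage, contradictory) yields 0 with
#'   a warning.
#' @export
random_overlap_probability <- function(table) {
  stopifnot(inherits(table, "overlap_table"))
  prod_log <- function(c_vals) {
    if (any(c_vals == 0)) {
      warning("C = 0 row: observed overlap with zero patch coverage")
      return(0)
    }
    exp(sum(log(c_vals)))
  }
  list(p_full = prod_log(table$C), p_table = prod_log(table$C_table),
       n = nrow(table))
}

#' Fraction of fission sites colocalizing with a detectable patch
#'
#' @param fission_events event table with `frame`, `position`.
#' @param patches patch table (`onset`, `offset`, `start`, `end`).
#' @return fraction of events whose position lies inside a patch extent
#'   active at the call frame.
#' @export
colocalization_fraction <- function(fission_events, patches) {
  if (!nrow(fission_events)) stop("no fission events")
  hits <- vapply(seq_len(nrow(fission_events)), function(i) {
    ev <- fission_events[i, ]
    act <- patches[patches$onset <= ev$frame & patches$offset >= ev$frame, ,
                   drop = FALSE]
    nrow(act) && any(ev$position >= act$start & ev$position < act$end)
  }, logical(1))
  mean(hits)
}

#' Reference overlap dataset of 20 fission events
#'
#' The published 20-event dataset of mitochondrion length (A), summed actin
#' patch length at the time of fission (B), and occupancy proportion
#' (C = B/A) bundled with the package, used as the worked example for the
#' random-overlap statistic.
#'
#' @return an [overlap_table()] of 20 rows.
#' @export
reference_overlap_table <- function() {
  path <- system.file("extdata", "fission_overlap_reference.csv",
                      package = "mitoaxon", mustWork = TRUE)
  tab <- utils::read.csv(path)
  overlap_table(tab$mito_length_um, tab$summed_patch_length_um)
}
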
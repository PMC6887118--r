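#' Mitochondrial density per 10 um of axon
#'
#' @param segments segment table for one frame (or any set of segments to be
#'   counted). Overlap-flagged segments count toward density (each flagged
#'   region holds at least one mitochondrion) even though they are excluded
#'   from length statistics; the choice is recorded in the result attribute.
#' @param sampled_length length of sampled axon in um.
#' @return mitochondria per 10 um, with attribute
#'   `counts_overlap_excluded = TRUE`.
#' @export
measure_density <- function(segments, sampled_length) {
  if (sampled_length <= 0) stop("sampled_length must be > 0")
  n <- if (is.null(segments)) 0L else nrow(segments)
  structure(10 * n / sampled_length, counts_overlap_excluded = TRUE)
}

#' Mean mitochondrial length over a segment table
#'
#' Overlap-flagged segments are excluded (their apparent length spans more
#' than one mitochondrion).
#' @param segments segment table.
#' @return mean length in um (NA if no usable segment).
#' @export
mean_mito_length <- function(segments) {
  if (is.null(segments) || !nrow(segments)) return(NA_real_)
  keep <- !segments$excluded_overlap
  if (!any(keep)) return(NA_real_)
  mean(segments$length[keep])
}

#' Collateral branch density per 100 um of axon
#'
#' Projections strictly longer than 10 um are branches.
#' @param projection_lengths lengths of axonal projections in um.
#' @param axon_length axon length in um.
#' @return list with `n_branches` and `per_100um`.
#' @export
branch_density <- function(projection_lengths, axon_length) {
  if (axon_length <= 0) stop("axon_length must be > 0")
  if (any(projection_lengths < 0)) stop("projection lengths must be >= 0")
  n <- sum(projection_lengths > BRANCH_LENGTH_UM)
  list(n_branches = n, per_100um = 100 * n / axon_length)
}

#' Mitochondrial mass index
#'
#' The dimensionless product of mean length (um) and density (per 10 um),
#' an index of total mitochondrial content per unit axon.
#' @param mean_length mean mitochondrial length, um.
#' @param density mitochondria per 10 um.
#' @return the product.
#' @export
mito_mass <- function(mean_length, density) {
  if (mean_length < 0 || density < 0) stop("inputs must be >= 0")
  mean_length * as.numeric(density)
}
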
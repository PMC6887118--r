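#' Total integrated fluorescence of a region of interest
#'
#' The ROI area multiplied by the background-subtracted mean intensity of
#' the stain. Negative background-subtracted means clip to zero with a
#' warning. Background should come from a stain-free region; the median is
#' the recommended estimator (robust to bright outliers).
#'
#' @param roi_pixels numeric vector of ROI pixel intensities.
#' @param background background intensity (scalar).
#' @param pixel_size optional um per pixel, to also report area in um^2.
#' @return list: `area_px`, `area_um2` (NA without `pixel_size`),
#'   `mean_intensity`, `background`, `total_integrated`.
#' @export
integrated_intensity <- function(roi_pixels, background, pixel_size = NULL) {
  if (!length(roi_pixels)) stop("empty ROI")
  m <- mean(roi_pixels)
  net <- m - background
  if (net < 0) {
    warning("mean intensity below background; clipping to 0")
    net <- 0
  }
  area <- length(roi_pixels)
  list(area_px = area,
       area_um2 = if (is.null(pixel_size)) NA_real_ else
         area * pixel_size^2,
       mean_intensity = m, background = background,
       total_integrated = area * net)
}

#' FRAP trace with the 90% bleach inclusion rule
#'
#' @param pre_bleach mean intensity before photobleaching.
#' @param post_bleach mean intensity immediately after (time 0).
#' @param time_s timepoint times in seconds.
#' @param intensity timepoint mean intensities.
#' @return list of class `frap_trace` with an `include` flag: only traces
#'   photobleached by at least 90% of their initial value qualify.
#' @export
frap_trace <- function(pre_bleach, post_bleach, time_s, intensity) {
  stopifnot(length(time_s) == length(intensity), pre_bleach > 0)
  structure(list(pre_bleach = pre_bleach, post_bleach = post_bleach,
                 time_s = time_s, intensity = intensity,
                 include = post_bleach <= FRAP_MAX_POSTBLEACH_FRACTION *
                   pre_bleach),
            class = "frap_trace")
}

#' Relative FRAP recovery per timepoint
#'
#' Percent recovery from the time-0 value toward the pre-bleach value:
#' 100 * (I_t - I_0) / (I_pre - I_0). Traces failing the 90% bleach rule
#' are excluded with the reason recorded; recovery is 0% at time 0 by
#' construction and invariant to global intensity rescaling.
#'
#' @param trace a [frap_trace()].
#' @return data.frame with `time_s` and `recovery_pct`, or `NULL` (with a
#'   warning stating the reason) when the trace is excluded.
#' @export
frap_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (!trace$include) {
    warning("trace excluded: photobleached by less than 90% of initial value")
    return(NULL)
  }
  denom <- trace$pre_bleach - trace$post_bleach
  if (denom <= 0) {
    warning("trace excluded: pre-bleach intensity not above post-bleach")
    return(NULL)
  }
  data.frame(time_s = trace$time_s,
             recovery_pct = 100 * (trace$intensity - trace$post_bleach) /
               denom)
}
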
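#' Annotated axon path
#'
#' A polyline through the image in micrometer coordinates, oriented so that
#' increasing arc-length runs anterograde (soma to growth cone).
#'
#' @param vertices two-column matrix (x, y in um) with at least 2 rows.
#' @param growth_cone_boundary arc-length (um) of the growth-cone neck, or
#'   `NULL` if not annotated (a fallback of path length minus 10 um is then
#'   used by [distal_sampling_window()], treating the distal 10 um of shaft
#'   as growth cone).
#' @return an object of class `axon_path` with the cumulative arc length.
#' @export
axon_path <- function(vertices, growth_cone_boundary = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2 || ncol(vertices) != 2) {
    stop("path needs at least 2 (x, y) vertices")
  }
  seg <- sqrt(rowSums(diff(vertices)^2))
  if (sum(seg) <= 0) stop("path must have strictly positive length")
  arc <- c(0, cumsum(seg))
  if (!is.null(growth_cone_boundary) &&
      (growth_cone_boundary <= 0 || growth_cone_boundary > sum(seg))) {
    stop("growth_cone_boundary must lie within the path extent")
  }
  structure(list(vertices = vertices, arc = arc, length = sum(seg),
                 growth_cone_boundary = growth_cone_boundary),
            class = "axon_path")
}

#' Straight path along the center row of a rendered strip
#' @param config a [sim_config()].
#' @param height strip height in pixels used at render time.
#' @return an [axon_path()].
#' @export
default_path <- function(config, height = 7L) {
  y <- ((height + 1L) %/% 2L - 0.5) * config$pixel_size
  axon_path(rbind(c(0, y), c(config$axon_length, y)))
}

# Interpolate (x, y) at arc-length positions s along the polyline.
path_point <- function(path, s) {
  x <- stats::approx(path$arc, path$vertices[, 1], s, rule = 2)$y
  y <- stats::approx(path$arc, path$vertices[, 2], s, rule = 2)$y
  cbind(x, y)
}

#' Distal sampling window for morphometry
#'
#' The 50 um window ending at the growth-cone neck, the region sampled for
#' mitochondrial length/density and immunofluorescence quantification. When
#' no neck is annotated, the distal 10 um of the shaft is treated as growth
#' cone and excluded.
#'
#' @param path an [axon_path()].
#' @param window window length in um (default 50).
#' @param gc_fallback growth-cone exclusion used when no boundary is
#'   annotated (default 10 um).
#' @return numeric `c(from, to)` arc-length interval in um.
#' @export
distal_sampling_window <- function(path, window = 50, gc_fallback = 10) {
  boundary <- if (!is.null(path$growth_cone_boundary)) {
    path$growth_cone_boundary
  } else {
    path$length - gc_fallback
  }
  if (boundary - window <= 0) {
    stop("path too short: the ", window,
         " um window would extend past the soma (boundary at ",
         round(boundary, 1), " um)")
  }
  c(boundary - window, boundary)
}
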
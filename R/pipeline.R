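#' Run the full analysis pipeline on one axon
#'
#' Orchestrates profile extraction, segmentation, track linking, fission and
#' fusion calling, motility classification and run decomposition, patch and
#' Drp1 detection with classification, the overlap table, and summary
#' morphometry for a single axon's stacks.
#'
#' @param stacks named list of arrays (`mito` required; `actin`, `drp1`
#'   optional), as from [render_stack()] or [read_fixture()].
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @param path optional [axon_path()] (default: straight center row).
#' @param params optional list of parameter overrides: `k_sigma`,
#'   `overlap_factor`, `transect_width`, `search`, `cv_tol`.
#' @return list with `series`, `segments`, `linked`, `fission`, `fusion`,
#'   `motility`, `runs`, `patches`, `overlap_table`, `summary`, and
#'   `provenance` (parameters used).
#' @export
analyze_axon <- function(stacks, pixel_size, frame_interval, path = NULL,
                         params = list()) {
  if (is.null(stacks$mito)) stop("a 'mito' channel stack is required")
  prm <- utils::modifyList(list(k_sigma = 3, overlap_factor = 1.6,
                                transect_width = 5 * pixel_size,
                                search = 10L, cv_tol = 0.15), params)
  series <- extract_profiles(stacks$mito, path = path,
                             pixel_size = pixel_size,
                             frame_interval = frame_interval,
                             width = prm$transect_width, channel = "mito")
  segments <- segment_series(series, k_sigma = prm$k_sigma,
                             overlap_factor = prm$overlap_factor)
  linked <- link_tracks(segments)
  fission <- detect_fission(linked, series, search = prm$search)
  fusion <- detect_fusion(linked, series, cv_tol = prm$cv_tol)

  ids <- if (!is.null(linked$tracks) && nrow(linked$tracks)) {
    unique(linked$tracks$track)
  } else integer(0)
  motility <- do.call(rbind, lapply(ids, function(id) {
    tr <- linked$tracks[linked$tracks$track == id, ]
    cm <- classify_motility(tr, frame_interval)
    data.frame(track = id, class = cm$class,
               max_excursion = cm$max_excursion,
               pct_time_moving = percent_time_moving(tr))
  }))
  runs <- do.call(rbind, lapply(ids, function(id) {
    r <- extract_runs(linked$tracks[linked$tracks$track == id, ],
                      frame_interval)
    if (nrow(r)) cbind(track = id, r) else NULL
  }))

  patches <- NULL
  for (ch in intersect(names(stacks), c("actin", "drp1"))) {
    ps_series <- extract_profiles(stacks[[ch]], path = path,
                                  pixel_size = pixel_size,
                                  frame_interval = frame_interval,
                                  width = prm$transect_width, channel = ch)
    p <- detect_patches(ps_series, channel = ch)
    if (nrow(p)) {
      p <- classify_patches(p, linked$tracks, fission,
                            frame_interval = frame_interval)
      patches <- rbind(patches, p)
    }
  }

  otab <- if (nrow(fission) && !is.null(patches) &&
              any(patches$channel == "actin")) {
    build_overlap_table(fission, patches, linked$tracks)
  } else NULL

  seg0 <- segments[segments$frame == 0, , drop = FALSE]
  sampled <- ncol(series$profile) * pixel_size
  dens <- measure_density(seg0, sampled)
  len <- mean_mito_length(seg0)
  list(series = series, segments = segments, linked = linked,
       fission = fission, fusion = fusion, motility = motility,
       runs = runs, patches = patches, overlap_table = otab,
       summary = data.frame(
         n_mito_frame0 = nrow(seg0), density_per_10um = as.numeric(dens),
         mean_length_um = len,
         mito_mass = if (is.na(len)) NA_real_ else mito_mass(len, dens),
         n_fission = nrow(fission), n_fusion = nrow(fusion)),
       provenance = prm)
}

#' Batch pipeline over fixture directories
#'
#' Runs [analyze_axon()] on each fixture bundle, writes per-axon CSV/JSON
#' outputs and a provenance log. Per-axon failures are recorded and
#' skipped; the call fails only if every axon fails.
#'
#' @param fixture_dirs character vector of fixture directories
#'   ([write_fixture()] layout).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param params parameter overrides passed to [analyze_axon()].
#' @return list of per-axon results (errors as `try-error`), invisibly
#'   annotated with the output paths.
#' @export
run_pipeline <- function(fixture_dirs, out_dir = NULL, params = list()) {
  if (!length(fixture_dirs)) stop("empty input manifest")
  missing <- fixture_dirs[!dir.exists(fixture_dirs)]
  if (length(missing)) stop("missing inputs: ", paste(missing, collapse = ", "))
  results <- list()
  for (d in fixture_dirs) {
    res <- try({
      fx <- read_fixture(d)
      analyze_axon(fx$stacks, pixel_size = fx$config$pixel_size,
                   frame_interval = fx$config$frame_interval,
                   params = params)
    }, silent = TRUE)
    results[[basename(d)]] <- res
  }
  failed <- vapply(results, inherits, logical(1), "try-error")
  if (all(failed)) stop("all inputs failed; first error: ",
                        attr(results[[1]], "condition")$message)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)[!failed]) {
      r <- results[[nm]]
      base <- file.path(out_dir, nm)
      utils::write.csv(r$linked$tracks, paste0(base, "_tracks.csv"),
                       row.names = FALSE)
      utils::write.csv(rbind(r$fission[, c("kind", "frame", "position")],
                             r$fusion[, c("kind", "frame", "position")]),
                       paste0(base, "_events.csv"), row.names = FALSE)
      if (!is.null(r$runs)) {
        utils::write.csv(r$runs, paste0(base, "_runs.csv"),
                         row.names = FALSE)
      }
      if (!is.null(r$patches)) {
        utils::write.csv(r$patches, paste0(base, "_patches.csv"),
                         row.names = FALSE)
      }
      utils::write.csv(r$summary, paste0(base, "_summary.csv"),
                       row.names = FALSE)
    }
    prov <- list(inputs = fixture_dirs,
                 failures = names(results)[failed],
                 parameters = results[[which(!failed)[1]]]$provenance,
                 r_version = R.version.string,
                 timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(results)
}
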
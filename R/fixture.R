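#' Write a simulated fixture bundle to disk
#'
#' Writes multi-page TIFF stacks (one file per channel, 16-bit, with the
#' count scale recorded in the config so values round-trip), the
#' ground-truth event log as JSON, the true track table as CSV, and the
#' simulation configuration as YAML.
#'
#' @param truth an [axon_truth()].
#' @param stacks named list of arrays from [render_stack()] (may be `NULL`
#'   to write truth only).
#' @param dir output directory (created if missing).
#' @param max_count full-scale count value for 16-bit TIFF encoding.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(truth, stacks, dir, max_count = 4096) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir)
  }
  for (ch in names(stacks)) {
    stk <- stacks[[ch]]
    pages <- lapply(seq_len(dim(stk)[3]), function(f) {
      pmin(pmax(stk[, , f] / max_count, 0), 1)
    })
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16L)
  }
  events <- list(
    fission = truth$fission_events,
    fusion = truth$fusion_events,
    patches = truth$patches,
    constrictions = truth$constrictions
  )
  jsonlite::write_json(events, file.path(dir, "events.json"),
                       dataframe = "columns", digits = NA)
  utils::write.csv(truth$tracks, file.path(dir, "tracks.csv"),
                   row.names = FALSE)
  cfg <- unclass(truth$config)
  cfg$fate_prob_filopodium <- as.list(cfg$fate_prob_filopodium)
  cfg$max_count <- max_count
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a fixture bundle written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `truth` (an [axon_truth()]), `stacks` (named list of
#'   arrays in counts), and `config`.
#' @export
read_fixture <- function(dir) {
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  max_count <- cfg_raw$max_count
  cfg_raw$max_count <- NULL
  cfg_raw$fate_prob_filopodium <- unlist(cfg_raw$fate_prob_filopodium)
  config <- do.call(sim_config, cfg_raw)

  ev <- jsonlite::read_json(file.path(dir, "events.json"),
                            simplifyVector = TRUE)
  tracks <- utils::read.csv(file.path(dir, "tracks.csv"))
  json_df <- function(x) {
    if (is.data.frame(x) && nrow(x)) return(x)
    if (is.list(x) && length(x) && max(lengths(x)) > 0) {
      return(as.data.frame(lapply(x, unlist)))
    }
    NULL  # empty: axon_truth supplies the schema
  }
  truth <- axon_truth(config, tracks,
                      fission_events = json_df(ev$fission),
                      fusion_events = json_df(ev$fusion),
                      patches = json_df(ev$patches),
                      constrictions = json_df(ev$constrictions))

  stacks <- list()
  for (ch in c("mito", "actin", "drp1")) {
    path <- file.path(dir, paste0(ch, ".tif"))
    if (file.exists(path)) {
      pages <- tiff::readTIFF(path, all = TRUE)
      stk <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                              length(pages)))
      for (f in seq_along(pages)) stk[, , f] <- pages[[f]] * max_count
      stacks[[ch]] <- stk
    }
  }
  list(truth = truth, stacks = stacks, config = config)
}
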
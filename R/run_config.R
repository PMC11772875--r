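# Run configuration: every threshold the pipeline uses lives here, with the
# published defaults (volume gate 0.05 um^3; spot-spot < 0.2 um; spot-surface
# < 0.1 um; surface-surface <= 0 um; 0.2 um diameter spots). Unknown keys are
# rejected so a typo cannot silently fall back to a default.

default_thresholds <- function() {
  list(min_volume_um3 = 0.05,
       spot_spot_um = 0.2,
       spot_surface_um = 0.1,
       surface_surface_um = 0,
       spot_diameter_um = 0.2)
}

#' Build a validated run configuration
#'
#' @param input path to an input OME-TIFF, or `NULL` when `scene` is given.
#' @param output_dir directory for result tables and the manifest.
#' @param channels named list or vector mapping channel index to role.
#' @param thresholds named list; defaults are the published analysis
#'   constants (see [default_thresholds()]); partial lists are completed.
#' @param tracking list with `gate_um` (default 2) and `max_gap` (default 1).
#' @param seed integer seed for all stochastic steps.
#' @param scene optional [scene_spec] list used by the simulate stage.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = ".", channels = NULL,
                       thresholds = list(), tracking = list(), seed = 1L,
                       scene = NULL) {
  th <- modifyList(default_thresholds(), as.list(thresholds))
  extra <- setdiff(names(th), names(default_thresholds()))
  if (length(extra)) stop("unknown threshold key(s): ",
                          paste(extra, collapse = ", "))
  if (any(unlist(th) < 0)) stop("thresholds must be >= 0")
  tr <- modifyList(list(gate_um = 2, max_gap = 1L), as.list(tracking))
  extra <- setdiff(names(tr), c("gate_um", "max_gap"))
  if (length(extra)) stop("unknown tracking key(s): ",
                          paste(extra, collapse = ", "))
  if (tr$gate_um <= 0) stop("tracking gate must be > 0")
  structure(list(input = input, output_dir = output_dir, channels = channels,
                 thresholds = th, tracking = tr, seed = as.integer(seed),
                 scene = scene),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys must be a subset of the [run_config()] arguments; unknown
#' keys are an error.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(y), known)
  if (length(extra)) stop("unknown config key(s): ",
                          paste(extra, collapse = ", "))
  if (!is.null(y$scene)) y$scene <- do.call(scene_spec, y$scene)
  do.call(run_config, y)
}

#' Write result tables plus a reproducibility manifest
#'
#' Each table is written as CSV with its column order preserved; a
#' `manifest.json` records configuration, seed, package version, file list
#' and a timestamp (the only field allowed to differ between identical runs).
#'
#' @param tables named list of data frames (e.g. `objects`, `tracks`,
#'   `comparisons`).
#' @param out_dir output directory, created if needed.
#' @param config optional `run_config` echoed into the manifest.
#' @param seed seed echoed into the manifest.
#' @return invisibly, the manifest path.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create '", out_dir, "'")
  }
  stopifnot(is.list(tables), !is.null(names(tables)))
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(
    package = "condensatr",
    version = as.character(packageVersion("condensatr")),
    seed = seed,
    config = if (is.null(config)) NULL else unclass(config),
    files = files,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA, force = TRUE)
  invisible(mf)
}
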
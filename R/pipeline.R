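# Config-driven orchestration: simulate (optional) -> segment -> measure ->
# associate -> (track) -> report. Every threshold and the seed are echoed
# into the run manifest; a stage failure propagates with its stage name and
# leaves earlier outputs on disk.

#' Run the full pipeline from a configuration
#'
#' When `config$scene` is present a synthetic scene is generated (and
#' written as OME-TIFF next to the results); otherwise `config$input` is
#' read. The condensate channel is segmented and measured, the organelle
#' channel (if any) classified against, and per-object / summary tables
#' plus a JSON manifest written to `config$output_dir`.
#'
#' @param config a `run_config` (or path to a YAML config).
#' @return a `pipeline_report`: list of stage outputs, warnings and file
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  report <- list(stages = character(0), warnings = character(0),
                 seed = config$seed)
  stage <- function(name, expr) {
    report$stages <<- c(report$stages, name)
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        report$warnings <<- c(report$warnings,
                              paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  truth <- NULL
  stack <- stage("input", {
    if (!is.null(config$scene)) {
      spec <- config$scene
      spec$seed <- config$seed
      sc <- generate_scene(spec)
      truth <- sc$truth
      if (!dir.exists(config$output_dir))
        dir.create(config$output_dir, recursive = TRUE)
      write_stack(sc$stack, file.path(config$output_dir, "scene.ome.tiff"))
      sc$stack
    } else {
      if (is.null(config$input)) stop("no input and no scene in config")
      read_stack(config$input,
                 metadata_overrides =
                   if (is.null(config$channels)) list()
                   else list(channel_roles = unlist(config$channels)))
    }
  })

  th <- config$thresholds
  cset <- stage("segment", segment_condensates(
    stack, min_volume_um3 = th$min_volume_um3))
  cset <- stage("measure", compute_morphometry(cset, stack))

  has_org <- "organelle" %in% stack$channel_roles
  if (has_org) {
    ofield <- stage("segment_organelle", segment_organelle(stack))
    cset <- stage("associate",
                  assign_association(cset, ofield,
                                     threshold_um = th$surface_surface_um))
  }

  tables <- list(objects = cset$objects)

  nt <- dim(stack$data)[1]
  if (nt >= 2) {
    tracks <- stage("track", {
      per_frame <- lapply(seq_len(nt), function(f)
        segment_condensates(stack, frame = f,
                            min_volume_um3 = th$min_volume_um3))
      link_tracks(per_frame, gate_um = config$tracking$gate_um,
                  max_gap = config$tracking$max_gap)
    })
    tables$tracks <- tracks
  }

  if (!is.null(truth) && nrow(truth$objects) > 0 && has_org) {
    tables$association_summary <- stage("report", {
      o <- cset$objects
      data.frame(n_objects = nrow(o),
                 n_associated = sum(o$assoc_class == "associated"),
                 n_cytoplasmic = sum(o$assoc_class == "cytoplasmic"),
                 frac_associated = mean(o$assoc_class == "associated"))
    })
  }

  mf <- stage("write", write_results(tables, config$output_dir,
                                     config = config, seed = config$seed))
  report$tables <- tables
  report$manifest <- mf
  report$truth <- truth
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> stages:", paste(x$stages, collapse = " -> "), "\n")
  if (length(x$warnings))
    cat("  warnings:\n   ", paste(x$warnings, collapse = "\n    "), "\n")
  cat("  manifest:", x$manifest, "\n")
  invisible(x)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `segment`, `run` (full pipeline)
#' and `version`. Intended to be called from `Rscript` via the
#' `inst/cli/condensatr` script; structured logs go to stderr, data to
#' files only.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: condensatr <command> [options]",
    "commands:",
    "  simulate --config <yaml> --seed <int> --out <dir>   generate a scene",
    "  run      --config <yaml> --seed <int> --out <dir>   full pipeline",
    "  segment  --in <ome-tiff> --out <dir>                segment + measure",
    "  version                                             print version",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  status <- 0L
  if (cmd == "version") {
    cat(as.character(packageVersion("condensatr")), "\n")
  } else if (cmd == "simulate") {
    spec <- if (!is.null(opts$config)) read_scene_spec(opts$config)
            else scene_spec()
    if (!is.null(opts$seed)) spec$seed <- as.integer(opts$seed)
    out <- opts$out %||% "."
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    sc <- generate_scene(spec)
    write_stack(sc$stack, file.path(out, "scene.ome.tiff"))
    write_ground_truth(sc$truth, file.path(out, "ground_truth.json"))
    message("wrote scene + ground truth to ", out)
  } else if (cmd == "run") {
    if (is.null(opts$config) || is.null(opts$seed) || is.null(opts$out))
      stop("run requires --config, --seed and --out")
    config <- read_run_config(opts$config)
    config$seed <- as.integer(opts$seed)
    config$output_dir <- opts$out
    rep <- run_pipeline(config)
    message("pipeline complete: ", rep$manifest)
  } else if (cmd == "segment") {
    if (is.null(opts$`in`) || is.null(opts$out))
      stop("segment requires --in and --out")
    stack <- read_stack(opts$`in`)
    cset <- compute_morphometry(
      segment_condensates(stack), stack)
    write_results(list(objects = cset$objects), opts$out)
    message("wrote object table to ", opts$out)
  } else {
    message("unknown command: ", cmd, "\n", usage)
    status <- 1L
  }
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("missing value for --", key)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}
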
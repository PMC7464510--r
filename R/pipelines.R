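#' Build and validate a run configuration
#'
#' One configuration object drives every pipeline: defaults are
#' overridden by the fields supplied here (and, at the command line, by
#' flags layered on top). Unknown keys are rejected rather than
#' silently ignored, and every run writes its fully resolved
#' configuration next to its outputs so the analysis is reproducible
#' from that file alone.
#'
#' @param pipeline one of `"accumulate"`, `"classify"`,
#'   `"concentration"`, `"synth"`.
#' @param input input image path, video frame directory, or glob of
#'   field images (not needed for `"synth"`).
#' @param output_dir directory for all artifacts (created if needed).
#' @param scale micrometres per pixel of the input imagery.
#' @param seed integer seed for every source of randomness.
#' @param detection named list of [detection_params()] overrides.
#' @param accumulation named list of [accumulation_params()] overrides
#'   plus optional `roi = c(x, y, r)` in pixels and `global_scale`.
#' @param bands named list of [hue_bands()] overrides.
#' @param tree named list of [tree_params()] overrides.
#' @param chamber named list of [chamber_geometry()] overrides.
#' @param synth named list: `what` (`"field"`, `"video"` or
#'   `"stained"`) plus overrides for the matching spec constructor.
#' @param verbose logical.
#' @return a list of class `run_config`.
#' @export
run_config <- function(pipeline, input = NULL, output_dir = "casa-out",
                       scale = 1, seed = 1L,
                       detection = list(), accumulation = list(),
                       bands = list(), tree = list(), chamber = list(),
                       synth = list(), verbose = TRUE) {
  pipeline <- match.arg(pipeline, c("accumulate", "classify",
                                    "concentration", "synth"))
  check_keys <- function(given, allowed, block) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) stop("unknown ", block, " key(s): ", paste(bad, collapse = ", "))
  }
  check_keys(detection, names(formals(detection_params)), "detection")
  check_keys(accumulation,
             c(names(formals(accumulation_params)), "roi", "global_scale"),
             "accumulation")
  check_keys(bands, names(formals(hue_bands)), "bands")
  check_keys(tree, names(formals(tree_params)), "tree")
  check_keys(chamber, names(formals(chamber_geometry)), "chamber")
  check_keys(synth, c("what", names(formals(field_spec)),
                      names(formals(motion_spec)), names(formals(stain_spec))),
             "synth")
  if (pipeline != "synth" && is.null(input)) stop("`input` is required for ", pipeline)
  structure(
    list(pipeline = pipeline, input = input, output_dir = output_dir,
         scale = scale, seed = as.integer(seed), detection = detection,
         accumulation = accumulation, bands = bands, tree = tree,
         chamber = chamber, synth = synth, verbose = verbose),
    class = "run_config"
  )
}

run_log <- function(config, con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
  if (config$verbose) message(msg)
  writeLines(msg, con)
}

resolve_inputs <- function(input) {
  files <- Sys.glob(input)
  if (length(files) == 0 && file.exists(input)) files <- input
  if (length(files) == 0) stop("input not found: ", input)
  files
}

#' Execute a configured pipeline
#'
#' Runs the pipeline named in the configuration and writes its
#' artifacts — CSV tables, JSON summaries, PNG heat maps — plus the
#' resolved configuration (`config.json`) and a log file into
#' `output_dir`. Identical configuration and seed yield identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return named list of the main in-memory results, invisibly; the
#'   files on disk are the primary product.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  set.seed(config$seed)
  jsonlite::write_json(config[setdiff(names(config), "verbose")],
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  run_log(config, logcon, "pipeline '%s' -> %s", config$pipeline, out)
  det <- do.call(detection_params, config$detection)
  res <- switch(config$pipeline,
    accumulate = pipeline_accumulate(config, det, logcon),
    classify = pipeline_classify(config, det, logcon),
    concentration = pipeline_concentration(config, det, logcon),
    synth = pipeline_synth(config, logcon)
  )
  run_log(config, logcon, "done")
  invisible(res)
}

pipeline_accumulate <- function(config, det, logcon) {
  acc_over <- config$accumulation
  roi <- acc_over$roi
  global_scale <- isTRUE(acc_over$global_scale)
  acc_over$roi <- NULL; acc_over$global_scale <- NULL
  if (is.null(acc_over$radius_px) && is.null(acc_over$radius_um)) {
    acc_over$radius_px <- 25
  }
  params <- do.call(accumulation_params, acc_over)
  frames <- if (dir.exists(config$input)) {
    read_video(config$input, scale = config$scale)
  } else {
    list(read_field(config$input, scale = config$scale))
  }
  run_log(config, logcon, "read %d frame(s) from %s", length(frames), config$input)
  psets <- lapply(frames, find_cells, params = det)
  maps <- heatmap_video(psets, params, global_scale = global_scale)
  heat_dir <- file.path(config$output_dir, "heatmaps")
  write_video(lapply(maps, render_heatmap, scale = config$scale), heat_dir)
  run_log(config, logcon, "wrote %d heat map frame(s)", length(maps))
  series <- NULL
  if (!is.null(roi)) {
    series <- roi_timeseries(psets, center_px = roi[1:2], radius_px = roi[3])
    utils::write.csv(tibble::as_tibble(series),
                     file.path(config$output_dir, "roi_series.csv"),
                     row.names = FALSE)
    run_log(config, logcon, "ROI r = %.3g px at (%.4g, %.4g): final pct_r %.4g%%",
            roi[3], roi[1], roi[2], series$pct_r[nrow(series)])
  }
  particles <- dplyr::bind_rows(lapply(psets, function(ps) {
    dplyr::mutate(tibble::as_tibble(ps), frame_index = attr(ps, "frame_index"),
                  .before = 1)
  }))
  utils::write.csv(particles, file.path(config$output_dir, "particles.csv"),
                   row.names = FALSE)
  list(maps = maps, series = series, particles = particles)
}

pipeline_classify <- function(config, det, logcon) {
  bands <- do.call(hue_bands, config$bands)
  tree <- do.call(tree_params, config$tree)
  frame <- read_field(config$input, scale = config$scale)
  cells <- classify_field(frame, det = det, bands = bands, tree = tree)
  summ <- summarize_functionality(cells)
  utils::write.csv(tibble::as_tibble(cells),
                   file.path(config$output_dir, "cells.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(total = summ$total,
         by_subtype = summ$by_subtype,
         pct_acrosome_intact = summ$pct_acrosome_intact,
         pct_membrane_intact = summ$pct_membrane_intact),
    file.path(config$output_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  run_log(config, logcon, "classified %d cell(s)", summ$total)
  list(cells = cells, summary = summ)
}

pipeline_concentration <- function(config, det, logcon) {
  geometry <- do.call(chamber_geometry, config$chamber)
  files <- resolve_inputs(config$input)
  per_field <- dplyr::bind_rows(lapply(files, function(f) {
    frame <- read_field(f, scale = config$scale)
    dplyr::mutate(estimate_concentration(frame, geometry, det), file = f,
                  .before = 1)
  }))
  agg <- aggregate_fields(per_field)
  utils::write.csv(per_field, file.path(config$output_dir, "concentration.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(glance(agg)),
                       file.path(config$output_dir, "concentration_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  run_log(config, logcon, "%d field(s): %.4g M cells/mL",
          agg$k, agg$mean_mcells_per_ml)
  list(per_field = per_field, aggregate = agg)
}

pipeline_synth <- function(config, logcon) {
  s <- config$synth
  what <- s$what %||% "field"
  s$what <- NULL
  s$seed <- s$seed %||% config$seed
  pick <- function(f) s[intersect(names(s), names(formals(f)))]
  out <- config$output_dir
  if (what == "field") {
    spec <- do.call(field_spec, pick(field_spec))
    gen <- make_field(spec)
    write_field(gen$frame, file.path(out, "field.png"))
    utils::write.csv(gen$truth, file.path(out, "truth.csv"), row.names = FALSE)
    run_log(config, logcon, "synthetic field: %d cells", nrow(gen$truth))
  } else if (what == "video") {
    field <- do.call(field_spec, pick(field_spec))
    motion <- do.call(motion_spec, pick(motion_spec))
    gen <- make_motion_video(field, motion, render = TRUE)
    write_video(gen$frames, file.path(out, "frames"))
    utils::write.csv(gen$truth, file.path(out, "truth.csv"), row.names = FALSE)
    run_log(config, logcon, "synthetic video: %d frames x %d cells",
            motion$n_frames, field$n_cells)
  } else if (what == "stained") {
    spec <- do.call(stain_spec, pick(stain_spec))
    gen <- make_stained_field(spec)
    write_field(gen$frame, file.path(out, "stained.png"))
    utils::write.csv(gen$truth, file.path(out, "truth.csv"), row.names = FALSE)
    run_log(config, logcon, "synthetic stained field: %d cells", nrow(gen$truth))
  } else {
    stop("unknown synth target: ", what)
  }
  gen
}
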
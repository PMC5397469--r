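#' Full pipeline configuration
#'
#' Bundles the stage parameters. Round-trips losslessly through JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param preprocess An [fp_params()].
#' @param detect A [detect_params()].
#' @param propagate A [propagation_params()].
#' @param id_cutoff_s IID/ID duration cutoff in seconds (default 5).
#' @param t0_application_s Solution-application time for latency computation.
#' @param reference_electrode Delay-map reference; `NULL` picks, per
#'   origin/class, the modal initiation electrode (ties broken
#'   lexicographically).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = fp_params(),
                            detect = detect_params(),
                            propagate = propagation_params(),
                            id_cutoff_s = 5,
                            t0_application_s = 0,
                            reference_electrode = NULL) {
  structure(list(preprocess = preprocess, detect = detect,
                 propagate = propagate, id_cutoff_s = id_cutoff_s,
                 t0_application_s = t0_application_s,
                 reference_electrode = reference_electrode),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    preprocess = do.call(fp_params, doc$preprocess),
    detect = do.call(detect_params, doc$detect),
    propagate = do.call(propagation_params, doc$propagate),
    id_cutoff_s = doc$id_cutoff_s,
    t0_application_s = doc$t0_application_s,
    reference_electrode = doc$reference_electrode)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

modal_electrode <- function(ids) {
  tab <- sort(table(ids), decreasing = TRUE)
  cand <- names(tab)[tab == tab[1]]
  sort(cand)[1]
}

#' Run the full analysis pipeline on a recording
#'
#' Executes preprocess (field-potential extraction) -> detect (per-electrode
#' events) -> propagate (network discharges, origins, delay maps) -> cycles
#' (cycle segmentation, latencies) -> stats (region parameters per epoch),
#' optionally writing the event/discharge/cycle tables, delay-map grids and
#' a machine-readable summary to `out_dir`. Stage failures propagate with
#' the stage name; no output files are left behind on failure. Rerunning
#' with the same recording and config is byte-identical.
#'
#' @param rec An [new_recording()] (raw or already at the target rate) or a
#'   path to an HDF5 container.
#' @param regions A [region_map()].
#' @param config A [pipeline_config()].
#' @param layout An [mea_layout()].
#' @param out_dir `NULL` or an output directory (created if needed).
#' @param verbose Log per-stage event counts to stderr.
#' @return List of class `ictomap_report`: `events`, `discharges`, `members`,
#'   `cycles`, `latencies`, `region_params`, `delay_maps` (named list of
#'   [delay_map()]s per origin x class), `counts`, `config`.
#' @export
run_pipeline <- function(rec, regions, config = pipeline_config(),
                         layout = mea_layout(), out_dir = NULL,
                         verbose = TRUE) {
  log_stage <- function(...) if (verbose) message("[ictomap] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (is.character(rec)) rec <- stage("read", read_recording(rec))
  if (!inherits(regions, "region_map"))
    stop("stage 'setup' failed: `regions` must be a region_map ",
         "(see read_region_map())", call. = FALSE)
  duration_s <- recording_duration(rec)
  epochs <- rec$epochs

  fp <- stage("preprocess", to_field_potential(rec, config$preprocess))
  rm(rec)   # the raw matrix can be large; only the field potentials are used
  log_stage("preprocess: ", ncol(fp$data), " samples/channel @ ",
            fp$sample_rate, " Hz")

  events <- stage("detect", detect_recording(fp, config$detect))
  log_stage("detect: ", nrow(events), " channel events")

  ds <- stage("propagate", {
    g <- group_events(events, config$propagate)
    annotate_discharges(g, regions, config$propagate, config$id_cutoff_s,
                        layout)
  })
  d <- ds$discharges
  log_stage("propagate: ", nrow(d), " network discharges (",
            sum(d$discharge_class == "IID"), " IID, ",
            sum(d$discharge_class == "ID"), " ID)")

  dmaps <- stage("propagate", {
    maps <- list()
    for (org in setdiff(unique(d$origin), "other")) {
      for (cls in c("IID", "ID")) {
        ids <- d$discharge_id[d$origin == org & d$discharge_class == cls]
        if (!length(ids)) next
        ref <- config$reference_electrode
        if (is.null(ref))
          ref <- modal_electrode(
            d$initiation_electrode[d$discharge_id %in% ids])
        maps[[paste(org, cls, sep = ".")]] <-
          suppressWarnings(average_delay_map(ds, ids, ref))
      }
    }
    maps
  })

  cycles <- stage("cycles", segment_cycles(d))
  latencies <- stage("cycles",
                     first_event_latencies(d, config$t0_application_s,
                                           duration_s))
  log_stage("cycles: ", nrow(cycles), " cycles (",
            sum(cycles$complete), " complete)")

  rp <- stage("stats", region_parameters(ds, regions, epochs = epochs,
                                         duration_s = duration_s))

  counts <- as.data.frame(table(origin = d$origin, class = d$discharge_class),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n"
  report <- structure(
    list(events = events, discharges = d, members = ds$members,
         cycles = cycles, latencies = latencies, region_params = rp,
         delay_maps = dmaps, counts = counts, config = config),
    class = "ictomap_report")
  if (!is.null(out_dir)) write_report(report, out_dir, layout)
  report
}

#' @export
print.ictomap_report <- function(x, ...) {
  cat("ictomap report\n")
  cat(sprintf("  %d channel events -> %d discharges, %d cycles (%d complete)\n",
              nrow(x$events), nrow(x$discharges), nrow(x$cycles),
              sum(x$cycles$complete)))
  for (i in seq_len(nrow(x$counts)))
    if (x$counts$n[i] > 0)
      cat(sprintf("  %s-origin %s: %d\n", x$counts$origin[i],
                  x$counts$class[i], x$counts$n[i]))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `events.csv`, `discharges.csv`, `cycles.csv`, `region_params.csv`,
#' `latencies.csv`, one `delay_map_<origin>_<class>.csv` 8x8 grid per
#' averaged map, and `summary.json`. All files are written only after every
#' stage has succeeded.
#'
#' @param report An `ictomap_report`.
#' @param out_dir Output directory.
#' @param layout Layout for grid export.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, layout = mea_layout()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    written <<- c(written, p)
  }
  wr(report$events, "events.csv")
  wr(report$discharges, "discharges.csv")
  wr(report$cycles, "cycles.csv")
  wr(report$latencies, "latencies.csv")
  wr(report$region_params, "region_params.csv")
  for (nm in names(report$delay_maps)) {
    p <- file.path(out_dir, paste0("delay_map_", gsub("\\.", "_", nm), ".csv"))
    utils::write.csv(delay_grid(report$delay_maps[[nm]], layout), p)
    written <- c(written, p)
  }
  cyc <- report$cycles
  complete <- cyc[cyc$complete, , drop = FALSE]
  summary <- list(
    n_events = nrow(report$events),
    n_discharges = nrow(report$discharges),
    counts = report$counts,
    cycle_stats = list(
      n_cycles = nrow(cyc),
      n_complete = nrow(complete),
      mean_n_iids = if (nrow(complete)) mean(complete$n_IIDs) else NA,
      mean_resting_s = if (any(!is.na(complete$resting_period_s)))
        mean(complete$resting_period_s, na.rm = TRUE) else NA),
    latencies = report$latencies,
    region_params = report$region_params,
    note = "p-values, where reported, are raw (no multiple-testing correction)",
    config = unclass_deep(report$config))
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  written <- c(written, p)
  ok <- TRUE
  invisible(out_dir)
}
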
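#' Discharge-grouping parameters
#'
#' @param group_window_s Single-linkage window for chaining per-electrode
#'   events into one network discharge (default 0.3 s, the same scale as the
#'   backward-propagation criterion: onsets further apart than this are
#'   treated as independent events).
#' @param backward_delay_limit_s A subiculum-initiated discharge whose CA1
#'   onset lags the subicular onset by no more than this is flagged as a
#'   conflicting grouping (default 0.3 s).
#' @param min_electrodes Discharges spanning fewer distinct electrodes are
#'   discarded as single-channel noise (default 3).
#' @param stray_lead_s A leading group of fewer than `min_electrodes` members
#'   separated from the rest of the discharge front by more than this onset
#'   gap is detached as stray (default 0.1 s). Propagation across the slice
#'   takes tens of milliseconds, so one or two electrodes "leading" the
#'   network by hundreds of milliseconds cannot be part of the same front —
#'   they are isolated noise triggers that would otherwise steal the
#'   initiation site.
#' @return A list of class `propagation_params`.
#' @export
propagation_params <- function(group_window_s = 0.3,
                               backward_delay_limit_s = 0.3,
                               min_electrodes = 3,
                               stray_lead_s = 0.1) {
  if (group_window_s < 0 || backward_delay_limit_s < 0 ||
      min_electrodes < 0 || stray_lead_s < 0)
    stop("propagation parameters must be >= 0")
  structure(list(group_window_s = group_window_s,
                 backward_delay_limit_s = backward_delay_limit_s,
                 min_electrodes = min_electrodes,
                 stray_lead_s = stray_lead_s),
            class = "propagation_params")
}

#' Group per-electrode events into network discharges
#'
#' Single-linkage chaining on onset times: an event joins a discharge if its
#' onset lies within `group_window_s` of any current member's onset (on the
#' time line this is equivalent to cutting the sorted onsets at gaps larger
#' than the window). At most one event per electrode belongs to a discharge —
#' the earliest wins; later same-electrode events within the chain are
#' discarded. Discharges with fewer than `min_electrodes` members are
#' dropped.
#'
#' @param events Event data.frame from [detect_recording()].
#' @param params A [propagation_params()].
#' @return List of class `discharge_set`: `discharges` (discharge_id,
#'   network_onset_s, n_electrodes) and `members` (the member events with
#'   their discharge_id).
#' @export
group_events <- function(events, params = propagation_params()) {
  if (nrow(events) == 0L) {
    return(structure(list(
      discharges = data.frame(discharge_id = character(),
                              network_onset_s = numeric(),
                              n_electrodes = integer(),
                              stringsAsFactors = FALSE),
      members = cbind(events, discharge_id = character(0))),
      class = "discharge_set"))
  }
  ev <- events[order(events$onset_s, events$electrode_id), , drop = FALSE]
  gap <- c(Inf, diff(ev$onset_s))
  cluster <- cumsum(gap > params$group_window_s)
  ev$discharge_id <- cluster
  # one event per electrode, earliest wins
  keep <- !duplicated(paste(cluster, ev$electrode_id))
  ev <- ev[keep, , drop = FALSE]
  # detach stray leaders: a < min_electrodes prefix separated from the rest
  # of the front by more than stray_lead_s cannot be part of the same
  # propagating discharge
  if (params$stray_lead_s > 0 && params$min_electrodes > 1) {
    drop <- logical(nrow(ev))
    for (cl in split(seq_len(nrow(ev)), ev$discharge_id)) {
      if (length(cl) < 2L) next
      on <- ev$onset_s[cl]            # sorted within cluster
      gaps <- diff(on)
      big <- which(gaps > params$stray_lead_s)
      big <- big[big < params$min_electrodes]
      if (length(big)) drop[cl[seq_len(max(big))]] <- TRUE
    }
    ev <- ev[!drop, , drop = FALSE]
  }
  sizes <- table(ev$discharge_id)
  ok <- names(sizes)[sizes >= params$min_electrodes]
  ev <- ev[ev$discharge_id %in% ok, , drop = FALSE]
  if (nrow(ev) == 0L) {
    empty <- events[0, , drop = FALSE]
    empty$discharge_id <- character(0)
    return(structure(list(
      discharges = data.frame(discharge_id = character(),
                              network_onset_s = numeric(),
                              n_electrodes = integer(),
                              stringsAsFactors = FALSE),
      members = empty), class = "discharge_set"))
  }
  ids <- unique(ev$discharge_id)
  new_id <- stats::setNames(sprintf("d%04d", seq_along(ids)), ids)
  ev$discharge_id <- unname(new_id[as.character(ev$discharge_id)])
  disch <- do.call(rbind, lapply(split(ev, ev$discharge_id), function(m)
    data.frame(discharge_id = m$discharge_id[1],
               network_onset_s = min(m$onset_s),
               n_electrodes = nrow(m), stringsAsFactors = FALSE)))
  disch <- disch[order(disch$network_onset_s), , drop = FALSE]
  rownames(disch) <- NULL
  rownames(ev) <- NULL
  structure(list(discharges = disch, members = ev), class = "discharge_set")
}

#' @export
print.discharge_set <- function(x, ...) {
  cat(sprintf("Discharge set: %d discharges, %d member events\n",
              nrow(x$discharges), nrow(x$members)))
  invisible(x)
}

#' Classify a discharge as interictal-like or ictal-like
#'
#' Events lasting more than `id_cutoff_s` seconds are ictal-like discharges
#' (IDs); all others are interictal-like (IIDs).
#'
#' @param duration_s Numeric vector of durations.
#' @param id_cutoff_s Cutoff in seconds (default 5).
#' @return Character vector, `"ID"` or `"IID"`.
#' @export
classify_type <- function(duration_s, id_cutoff_s = 5) {
  ifelse(duration_s > id_cutoff_s, "ID", "IID")
}

#' Origin label and propagation pattern of one discharge
#'
#' The region whose electrode first records the discharge is the initiation
#' site: CA3a/b initiation defines a CA3-origin discharge, subicular
#' initiation a Sub-origin discharge, anything else "other". For Sub-origin
#' discharges a CA1 member onset within `backward_delay_limit_s` of the
#' subicular onset contradicts the no-backward-propagation criterion and is
#' flagged as a conflicting grouping (not silently relabelled).
#'
#' @param members Member events of one discharge (rows of
#'   `discharge_set$members`).
#' @param regions A [region_map()].
#' @param params A [propagation_params()].
#' @param layout Layout used for the initiation tie-break.
#' @return List: `initiation_electrode`, `initiation_region`, `origin`,
#'   `pattern` (regions in onset order, "+"-separated), `conflict`.
#' @export
classify_origin <- function(members, regions, params = propagation_params(),
                            layout = mea_layout()) {
  m <- members[order(members$onset_s, members$electrode_id), , drop = FALSE]
  t0 <- min(m$onset_s)
  cand <- which(m$onset_s == t0)
  if (length(cand) > 1L) {
    # tie-break: electrode with the smallest mean delay to all other members,
    # then lexicographic id
    md <- vapply(cand, function(i)
      mean(abs(m$onset_s - m$onset_s[i])), 0)
    cand <- cand[md == min(md)]
    cand <- cand[order(m$electrode_id[cand])][1]
  }
  init_el <- m$electrode_id[cand]
  init_reg <- electrode_region(regions, init_el)
  origin <- if (init_reg %in% c("CA3a", "CA3b")) "CA3"
            else if (init_reg == "Sub") "Sub" else "other"
  regs <- electrode_region(regions, m$electrode_id)
  pattern <- paste(unique(regs[regs != "none"]), collapse = "+")
  conflict <- FALSE
  if (origin == "Sub") {
    ca1 <- m$onset_s[regs == "CA1"]
    if (length(ca1) && any(ca1 - t0 <= params$backward_delay_limit_s))
      conflict <- TRUE
  }
  list(initiation_electrode = init_el, initiation_region = init_reg,
       origin = origin, pattern = pattern, conflict = conflict)
}

#' Annotate grouped discharges with initiation, origin and class
#'
#' Adds, per discharge: the initiation electrode and region, the CA3/Sub
#' origin label, the propagation pattern, the duration measured at the
#' initiation electrode (the trace that defines the event), the IID/ID class
#' from that duration, and the Sub->CA1 conflict flag.
#'
#' @param ds A `discharge_set` from [group_events()].
#' @param regions A [region_map()].
#' @param params A [propagation_params()].
#' @param id_cutoff_s IID/ID duration cutoff in seconds (default 5).
#' @param layout An [mea_layout()].
#' @return The `discharge_set` with extended `discharges` columns
#'   (`initiation_electrode`, `initiation_region`, `origin`,
#'   `discharge_class`, `duration_s`, `offset_s`, `participating_regions`,
#'   `conflict`).
#' @export
annotate_discharges <- function(ds, regions, params = propagation_params(),
                                id_cutoff_s = 5, layout = mea_layout()) {
  d <- ds$discharges
  if (nrow(d) == 0L) {
    d$initiation_electrode <- character(0); d$initiation_region <- character(0)
    d$origin <- character(0); d$discharge_class <- character(0)
    d$duration_s <- numeric(0); d$offset_s <- numeric(0)
    d$participating_regions <- character(0); d$conflict <- logical(0)
    ds$discharges <- d
    return(ds)
  }
  mem <- split(ds$members, ds$members$discharge_id)
  ann <- lapply(d$discharge_id, function(id) {
    m <- mem[[id]]
    cl <- classify_origin(m, regions, params, layout)
    i <- which(m$electrode_id == cl$initiation_electrode)
    data.frame(initiation_electrode = cl$initiation_electrode,
               initiation_region = cl$initiation_region,
               origin = cl$origin,
               duration_s = m$duration_s[i],
               offset_s = m$offset_s[i],
               participating_regions = cl$pattern,
               conflict = cl$conflict, stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, ann)
  ann$discharge_class <- classify_type(ann$duration_s, id_cutoff_s)
  ds$discharges <- cbind(d, ann[, c("initiation_electrode", "initiation_region",
                                    "origin", "discharge_class", "duration_s",
                                    "offset_s", "participating_regions",
                                    "conflict")])
  ds
}

#' Relative onset-time delay map of one discharge
#'
#' Delay of every member electrode's onset relative to a reference electrode,
#' in milliseconds — the substrate of the onset-delay contour plots used to
#' localise initiation sites. Electrodes without a member event are absent.
#'
#' @param ds A `discharge_set`.
#' @param discharge_id Which discharge.
#' @param reference_electrode Must be a member of the discharge.
#' @return data.frame of class `delay_map` (`electrode_id`, `delay_ms`) with
#'   attribute `reference_electrode`. `delay_ms` is 0 at the reference and
#'   negative wherever an electrode led it.
#' @export
delay_map <- function(ds, discharge_id, reference_electrode) {
  m <- ds$members[ds$members$discharge_id == discharge_id, , drop = FALSE]
  if (nrow(m) == 0L) stop("unknown discharge_id: ", discharge_id)
  iref <- match(reference_electrode, m$electrode_id)
  if (is.na(iref))
    stop("reference electrode ", reference_electrode,
         " is not a member of discharge ", discharge_id)
  out <- data.frame(electrode_id = m$electrode_id,
                    delay_ms = (m$onset_s - m$onset_s[iref]) * 1000,
                    stringsAsFactors = FALSE)
  out <- out[order(out$electrode_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_electrode") <- reference_electrode
  class(out) <- c("delay_map", "data.frame")
  out
}

#' Average delay map over discharges of one origin
#'
#' Element-wise mean of the per-discharge [delay_map()]s over all discharges
#' in which an electrode participated; electrodes absent from every discharge
#' are absent from the average. Discharges in which the reference electrode
#' did not participate cannot contribute relative delays and are skipped with
#' a warning.
#'
#' @param ds A `discharge_set`.
#' @param discharge_ids Discharges to average (e.g. all of one origin/class).
#' @param reference_electrode Common reference electrode.
#' @return A `delay_map` with an `n_discharges` attribute.
#' @export
average_delay_map <- function(ds, discharge_ids, reference_electrode) {
  if (length(discharge_ids) == 0L) stop("no discharges to average")
  maps <- list()
  skipped <- 0L
  for (id in discharge_ids) {
    m <- ds$members[ds$members$discharge_id == id, , drop = FALSE]
    if (!reference_electrode %in% m$electrode_id) { skipped <- skipped + 1L; next }
    maps[[length(maps) + 1L]] <- delay_map(ds, id, reference_electrode)
  }
  if (skipped > 0L)
    warning(skipped, " discharge(s) skipped: reference electrode not a member")
  if (!length(maps))
    stop("reference electrode ", reference_electrode,
         " is a member of none of the given discharges")
  all_d <- do.call(rbind, maps)
  agg <- stats::aggregate(delay_ms ~ electrode_id, data = all_d, FUN = mean)
  agg <- agg[order(agg$electrode_id), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "reference_electrode") <- reference_electrode
  attr(agg, "n_discharges") <- length(maps)
  class(agg) <- c("delay_map", "data.frame")
  agg
}

#' Lay a delay map out on the 8x8 electrode grid
#'
#' @param dm A [delay_map()].
#' @param layout An [mea_layout()].
#' @return 8x8 numeric matrix (rows = grid rows, columns = grid columns) of
#'   delays in ms; `NA` at the void corners and at electrodes without a
#'   member event. Suitable for CSV export and external contour rendering.
#' @export
delay_grid <- function(dm, layout = mea_layout()) {
  g <- matrix(NA_real_, 8, 8,
              dimnames = list(row = paste0("r", 1:8), col = paste0("c", 1:8)))
  i <- match(dm$electrode_id, layout$electrode_id)
  g[cbind(layout$row[i], layout$col[i])] <- dm$delay_ms
  g
}
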
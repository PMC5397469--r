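#' Event-detection parameters
#'
#' Events are detected where the field potential deviates from the baseline
#' mean by more than `threshold_multiplier` baseline SDs (either polarity).
#' The onset is the first supra-threshold sample. Because only the onset is
#' classically defined, the offset rule is explicit and tunable: a moving-RMS
#' envelope of the deviation is compared against
#' `offset_hysteresis * threshold`; an event ends at the last
#' supra-hysteresis envelope sample before the envelope stays below that
#' level for at least `merge_gap_s`, and supra-threshold excursions separated
#' by shorter quiet gaps merge into one event.
#'
#' @param threshold_multiplier Threshold in baseline SDs (default 4).
#' @param baseline_window_s Length of the quiescent baseline window (0.5 s).
#' @param baseline_step_s Step of the sliding baseline search (0.1 s).
#' @param merge_gap_s Minimum quiet gap that terminates an event (0.3 s);
#'   chosen so multi-component IIDs (hundreds of ms) unify while successive
#'   IIDs seconds apart stay distinct.
#' @param offset_hysteresis Offset level as a fraction of the threshold (0.5).
#' @param min_event_s Events shorter than this are discarded (0.02 s).
#' @param envelope_window_s Length of the moving-RMS envelope used for the
#'   offset/quiet logic (0.05 s). Band-limited noise crosses fixed levels far
#'   too often for a per-sample quiet rule to terminate events, so event
#'   extent is judged on this short envelope of the deviation; the onset
#'   itself remains the first raw supra-threshold sample.
#' @param baseline_quantile Which quantile of the sliding-window SDs defines
#'   the baseline window (default 0.25). The strict minimum over thousands of
#'   windows is biased far below the true noise SD (an extreme-value
#'   artefact); the lower quartile still avoids discharge-containing windows
#'   whenever at least a quarter of the trace is quiescent, while estimating
#'   the noise floor nearly without bias.
#' @return A list of class `detect_params`.
#' @export
detect_params <- function(threshold_multiplier = 4,
                          baseline_window_s = 0.5,
                          baseline_step_s = 0.1,
                          merge_gap_s = 0.3,
                          offset_hysteresis = 0.5,
                          min_event_s = 0.02,
                          envelope_window_s = 0.05,
                          baseline_quantile = 0.25) {
  if (threshold_multiplier <= 0) stop("threshold_multiplier must be > 0")
  if (baseline_window_s <= 0) stop("baseline_window_s must be > 0")
  if (merge_gap_s < 0) stop("merge_gap_s must be >= 0")
  structure(list(threshold_multiplier = threshold_multiplier,
                 baseline_window_s = baseline_window_s,
                 baseline_step_s = baseline_step_s,
                 merge_gap_s = merge_gap_s,
                 offset_hysteresis = offset_hysteresis,
                 min_event_s = min_event_s,
                 envelope_window_s = envelope_window_s,
                 baseline_quantile = baseline_quantile),
            class = "detect_params")
}

#' Estimate the quiescent baseline of a trace
#'
#' Slides a `baseline_window_s` window across the trace in `baseline_step_s`
#' steps and selects a quiescent window by its SD rank — an automated
#' stand-in for the manual choice of a stretch free of epileptiform
#' discharges. The window at the `baseline_quantile` of the SD distribution
#' is used (the strict minimum is an extreme-value underestimate of the
#' noise floor; the lower quartile excludes discharge-containing windows as
#' long as at least that fraction of the trace is quiescent). Returns the
#' mean and SD of the selected window.
#'
#' @param x Numeric trace (uV).
#' @param sample_rate Sampling rate in Hz.
#' @param params A [detect_params()].
#' @return List of class `baseline_stats`: `mean`, `sd` (uV), and the window
#'   `start_s` / `end_s` relative to the start of `x`.
#' @export
estimate_baseline <- function(x, sample_rate, params = detect_params()) {
  w <- round(params$baseline_window_s * sample_rate)
  if (length(x) < w)
    stop("trace (", length(x), " samples) shorter than the baseline window (",
         w, " samples)")
  step <- max(1L, round(params$baseline_step_s * sample_rate))
  starts <- seq(1L, length(x) - w + 1L, by = step)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  s <- cs[starts + w] - cs[starts]
  s2 <- cs2[starts + w] - cs2[starts]
  v <- pmax(0, (s2 - s^2 / w) / (w - 1))
  # window whose SD sits at the target quantile of all window SDs
  target <- stats::quantile(v, params$baseline_quantile, type = 1, names = FALSE)
  i <- which(v == target)[1]
  structure(list(mean = s[i] / w, sd = sqrt(v[i]),
                 start_s = (starts[i] - 1) / sample_rate,
                 end_s = (starts[i] - 1 + w) / sample_rate),
            class = "baseline_stats")
}

# centred moving RMS (compiled)
moving_rms <- function(x, w) moving_rms_cpp(x, as.integer(w))

#' Detect epileptiform events on one trace
#'
#' Applies the baseline-referenced threshold rule: an event is confirmed when
#' the absolute deviation of the field potential from the baseline mean
#' exceeds `threshold_multiplier * baseline$sd`; the onset is the first
#' supra-threshold sample. See [detect_params()] for the offset/merge rule.
#'
#' @param x Numeric trace (uV).
#' @param sample_rate Sampling rate in Hz.
#' @param baseline A [estimate_baseline()] result (`sd` must be positive).
#' @param params A [detect_params()].
#' @param electrode_id Id recorded in the output (optional).
#' @param t_offset_s Added to all reported times (used when `x` is a slice of
#'   a longer recording).
#' @return data.frame with one row per event: `electrode_id`, `onset_s`,
#'   `offset_s`, `duration_s`, `peak_amplitude_uV` (max absolute deviation
#'   from the baseline mean), `peak_time_s`, `polarity`. Sorted by onset;
#'   events never overlap and are separated by at least `merge_gap_s` of
#'   sub-hysteresis signal.
#' @export
detect_events <- function(x, sample_rate, baseline, params = detect_params(),
                          electrode_id = NA_character_, t_offset_s = 0) {
  if (!inherits(baseline, "baseline_stats"))
    stop("`baseline` must come from estimate_baseline()")
  if (!is.finite(baseline$sd) || baseline$sd <= 0)
    stop("degenerate baseline: sd must be positive for threshold detection")
  thr <- params$threshold_multiplier * baseline$sd
  hyst <- params$offset_hysteresis * thr
  dev <- abs(x - baseline$mean)
  above <- dev > thr
  empty <- data.frame(electrode_id = character(), onset_s = numeric(),
                      offset_s = numeric(), duration_s = numeric(),
                      peak_amplitude_uV = numeric(), peak_time_s = numeric(),
                      polarity = character(), stringsAsFactors = FALSE)
  if (!any(above)) return(empty)
  gap_n <- max(1L, round(params$merge_gap_s * sample_rate))
  env <- moving_rms(dev, max(1L, round(params$envelope_window_s * sample_rate)))
  quiet <- env < hyst
  n <- length(x)
  # quiet runs long enough to terminate an event; a "gap start" is any
  # position from which the envelope stays quiet for >= gap_n samples
  r <- rle(quiet)
  rend <- cumsum(r$lengths)
  rstart <- rend - r$lengths + 1L
  ok <- r$values & r$lengths >= gap_n
  qs <- rstart[ok]
  qlast <- rend[ok] - gap_n + 1L   # last valid gap start within each run
  # onset candidates: supra-threshold samples whose envelope is also above
  # the hysteresis level. Isolated single-sample noise crossings with a
  # quiescent envelope cannot open (and thereby pre-date) an event; they
  # could never survive the minimum-duration filter anyway.
  idx_above <- which(above & !quiet)
  active <- which(!quiet)
  if (!length(idx_above)) return(empty)
  out <- list()
  o <- idx_above[1]
  repeat {
    # first gap start at or after the onset
    j <- findInterval(o - 1L, qlast) + 1L
    g <- if (j <= length(qs)) max(qs[j], o) else n + 1L
    acts <- active[active >= o & active <= g]
    offset_i <- if (length(acts)) max(acts) else o
    rng <- o:offset_i
    pk <- rng[which.max(dev[rng])]
    out[[length(out) + 1L]] <- data.frame(
      electrode_id = electrode_id,
      onset_s = (o - 1) / sample_rate + t_offset_s,
      offset_s = offset_i / sample_rate + t_offset_s,
      duration_s = (offset_i - o + 1) / sample_rate,
      peak_amplitude_uV = dev[pk],
      peak_time_s = (pk - 1) / sample_rate + t_offset_s,
      polarity = if (x[pk] - baseline$mean < 0) "negative" else "positive",
      stringsAsFactors = FALSE)
    nxt <- idx_above[idx_above > max(g, offset_i)]
    if (!length(nxt)) break
    o <- nxt[1]
  }
  ev <- do.call(rbind, out)
  ev <- ev[ev$duration_s >= params$min_event_s, , drop = FALSE]
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Detect events on every channel of a recording
#'
#' Runs [estimate_baseline()] and [detect_events()] per channel. When the
#' recording carries epoch annotations and `per_epoch = TRUE`, the baseline
#' is re-estimated within each epoch and detection runs epoch by epoch (drug
#' application can shift the noise floor); otherwise a single baseline per
#' channel is used.
#'
#' @param rec An [new_recording()] of field potentials.
#' @param params A [detect_params()].
#' @param per_epoch Re-estimate baselines per annotated epoch (default TRUE).
#' @param edge_guard_s Events whose onset lies within this many seconds of
#'   the recording start or end are dropped (default 0.5): the zero-phase
#'   band-pass inflates amplitudes near the recording edges (reflection
#'   padding), which otherwise shows up as a synchronous spurious
#'   "discharge" at time zero.
#' @return data.frame of events across channels, sorted by onset, with a
#'   `baselines` attribute (data.frame: electrode_id, epoch, mean, sd).
#' @export
detect_recording <- function(rec, params = detect_params(), per_epoch = TRUE,
                             edge_guard_s = 0.5) {
  fs <- rec$sample_rate
  spans <- if (per_epoch && !is.null(rec$epochs))
    rec$epochs[, c("label", "start_s", "end_s")]
  else data.frame(label = "all", start_s = 0,
                  end_s = recording_duration(rec))
  evs <- list(); bls <- list()
  for (ch in seq_along(rec$channels)) {
    for (k in seq_len(nrow(spans))) {
      i0 <- floor(spans$start_s[k] * fs) + 1L
      i1 <- min(ncol(rec$data), ceiling(spans$end_s[k] * fs))
      if (i1 - i0 + 1L < round(params$baseline_window_s * fs)) next
      x <- rec$data[ch, i0:i1]
      bl <- estimate_baseline(x, fs, params)
      bls[[length(bls) + 1L]] <- data.frame(
        electrode_id = rec$channels[ch], epoch = spans$label[k],
        mean = bl$mean, sd = bl$sd, stringsAsFactors = FALSE)
      evs[[length(evs) + 1L]] <- detect_events(
        x, fs, bl, params, electrode_id = rec$channels[ch],
        t_offset_s = (i0 - 1L) / fs)
    }
  }
  ev <- do.call(rbind, evs)
  if (is.null(ev))
    ev <- data.frame(electrode_id = character(), onset_s = numeric(),
                     offset_s = numeric(), duration_s = numeric(),
                     peak_amplitude_uV = numeric(), peak_time_s = numeric(),
                     polarity = character(), stringsAsFactors = FALSE)
  if (edge_guard_s > 0 && nrow(ev)) {
    dur <- recording_duration(rec)
    ev <- ev[ev$onset_s >= edge_guard_s & ev$onset_s <= dur - edge_guard_s, ,
             drop = FALSE]
  }
  ev <- ev[order(ev$onset_s, ev$electrode_id), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "baselines") <- do.call(rbind, bls)
  ev
}
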
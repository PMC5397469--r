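#' Segment a discharge sequence into recurring cycles
#'
#' A discharge cycle is an IID train followed by exactly one ID, after which
#' a resting period separates it from the next cycle. Segmentation rule: an
#' ID closes the current cycle; IIDs after an ID open the next one; leading
#' IIDs before the first ID form the first cycle; trailing IIDs without a
#' closing ID form an incomplete cycle. The resting period of a cycle is the
#' gap from its ID offset to the first onset of the next cycle (`NA` for the
#' last cycle). Cycles with fewer than 2 IIDs are flagged atypical.
#'
#' @param discharges Annotated discharge table (from [annotate_discharges()],
#'   the `discharges` element), possibly containing several origins; cycles
#'   are segmented per origin.
#' @param origins Which origin labels to segment (default: all present except
#'   "other").
#' @param include_conflicts Keep discharges whose grouping was flagged as
#'   conflicting (a subiculum-initiated discharge with a CA1 onset inside the
#'   backward-propagation limit; in practice a subicular event fused with a
#'   CA3-origin discharge arriving within the grouping window). Default
#'   `FALSE`: such fusions carry the other origin's duration and would close
#'   cycles spuriously.
#' @return data.frame: `origin`, `cycle_index`, `n_IIDs`, `cycle_start_s`,
#'   `cycle_end_s` (ID offset), `resting_period_s`, `complete`, `atypical`,
#'   `id_discharge_id`.
#' @export
segment_cycles <- function(discharges, origins = NULL,
                           include_conflicts = FALSE) {
  if (is.null(origins))
    origins <- setdiff(unique(discharges$origin), "other")
  if (!include_conflicts && !is.null(discharges$conflict))
    discharges <- discharges[!discharges$conflict, , drop = FALSE]
  out <- list()
  for (org in origins) {
    d <- discharges[discharges$origin == org, , drop = FALSE]
    d <- d[order(d$network_onset_s), , drop = FALSE]
    if (nrow(d) == 0L) next
    is_id <- d$discharge_class == "ID"
    # cycle index: IIDs after an ID belong to the next cycle
    cyc <- cumsum(c(0, head(is_id, -1))) + 1L
    for (k in unique(cyc)) {
      rows <- which(cyc == k)
      ids <- rows[is_id[rows]]
      n_iid <- sum(!is_id[rows])
      complete <- length(ids) == 1L
      end_s <- if (complete) d$offset_s[ids] else NA_real_
      # resting: gap from this ID offset to the next cycle's first onset
      nxt <- rows[length(rows)] + 1L
      resting <- if (complete && nxt <= nrow(d))
        d$network_onset_s[nxt] - end_s else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        origin = org, cycle_index = k, n_IIDs = n_iid,
        cycle_start_s = d$network_onset_s[rows[1]],
        cycle_end_s = end_s, resting_period_s = resting,
        complete = complete, atypical = n_iid < 2,
        id_discharge_id = if (complete) d$discharge_id[ids] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(origin = character(), cycle_index = integer(),
                      n_IIDs = integer(), cycle_start_s = numeric(),
                      cycle_end_s = numeric(), resting_period_s = numeric(),
                      complete = logical(), atypical = logical(),
                      id_discharge_id = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Latency from solution application to the first discharge of each kind
#'
#' @param discharges Annotated discharge table.
#' @param t0_application_s Time the pro-convulsant solution was applied
#'   (an input annotation, not inferred from the data).
#' @param duration_s Recording duration; if supplied, `t0` beyond it is an
#'   error.
#' @return data.frame `origin`, `class`, `latency_s` (earliest network onset
#'   at or after `t0`, minus `t0`); a missing origin/class combination is
#'   reported with `latency_s = NA`, not zero.
#' @export
first_event_latencies <- function(discharges, t0_application_s = 0,
                                  duration_s = NULL) {
  if (!is.null(duration_s) && t0_application_s > duration_s)
    stop("t0_application_s (", t0_application_s,
         " s) lies beyond the recording (", duration_s, " s)")
  grid <- expand.grid(origin = c("CA3", "Sub"), class = c("IID", "ID"),
                      stringsAsFactors = FALSE)
  grid$latency_s <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- discharges$origin == grid$origin[i] &
      discharges$discharge_class == grid$class[i] &
      discharges$network_onset_s >= t0_application_s
    if (any(sel))
      grid$latency_s[i] <- min(discharges$network_onset_s[sel]) - t0_application_s
  }
  grid
}
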
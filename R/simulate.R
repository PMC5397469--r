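#' Simulation configuration for synthetic slice recordings
#'
#' Describes a generative model of the recurrent epileptiform activity seen in
#' neonatal hippocampal slices under low-Mg2+ / high-K+ perfusion: two
#' independent renewal processes of discharge cycles (a train of
#' interictal-like discharges, IIDs, followed by exactly one ictal-like
#' discharge, ID, then a long resting period), one initiated in CA3a/b and
#' propagating anterogradely to CA1 and the subiculum and retrogradely to
#' CA3c and the DG, the other initiated in the subiculum and expressed there
#' only (no backward propagation to CA1). Events reach each electrode after
#' the cumulative inter-region edge delay plus an intra-region conduction
#' delay proportional to distance from the region entry point.
#'
#' Default distribution moments reproduce the study conditions summarised in
#' the package vignette: per-cycle IID counts `2 + Binomial(18, p)` with
#' support 2-20 and mean 8.19; resting periods `113 + 391 * Beta(2, b)` with
#' support 113-504 s and mean 241.23 s; first-event latencies uniform over
#' 180-290 s (CA3 IID), 230-1840 s (CA3 ID), 190-250 s (Sub IID), and
#' 280-1540 s (Sub ID).
#'
#' @param seed Integer seed; identical configs give bit-identical output.
#' @param duration_s Recording length in seconds.
#' @param sample_rate Sampling rate in Hz (default 20000, the acquisition
#'   rate; simulations meant for direct analysis at the field-potential rate
#'   may use 1000 or 500).
#' @param noise_sd Gaussian noise SD per sample per channel, uV.
#' @param origins Named list of origin specifications, see [origin_spec()].
#' @param drug_epochs `NULL` or data.frame(label, start_s, end_s, agent).
#' @param modulation Named list: epoch label -> named numeric rate multipliers
#'   in `[0, 1]` keyed `"<origin>.<class>"` (e.g. `CA3.ID = 0` abolishes
#'   CA3-origin IDs during that epoch). Missing keys default to 1.
#' @param id_cutoff_s Duration cutoff separating IIDs from IDs (5 s).
#' @param speed_um_per_s Intra-region conduction speed (default 5e4 um/s,
#'   i.e. 0.05 m/s: one 200 um electrode pitch adds 4 ms).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       duration_s = 3000,
                       sample_rate = 20000,
                       noise_sd = 10,
                       origins = default_origins(),
                       drug_epochs = NULL,
                       modulation = list(),
                       id_cutoff_s = 5,
                       speed_um_per_s = 5e4) {
  cfg <- structure(
    list(seed = as.integer(seed), duration_s = duration_s,
         sample_rate = sample_rate, noise_sd = noise_sd,
         origins = origins, drug_epochs = validate_epochs(drug_epochs),
         modulation = modulation, id_cutoff_s = id_cutoff_s,
         speed_um_per_s = speed_um_per_s),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Specification of one discharge origin
#'
#' @param initiation_electrode Electrode id acting as the pacemaker site.
#' @param latency_iid,latency_id `c(min, max)` of the uniform latency (s) from
#'   solution application to the first IID / first ID of this origin.
#' @param n_iid List `list(shift, size, prob)`: per-cycle IID count is
#'   `shift + Binomial(size, prob)`.
#' @param resting List `list(min, range, shape1, shape2)`: resting period is
#'   `min + range * Beta(shape1, shape2)` seconds.
#' @param iid_gap `c(min, max)` uniform onset-to-onset gap between successive
#'   IIDs within a cycle, seconds (cycles after the first; the first cycle
#'   stretches its gaps so that the drawn first-ID latency is honoured).
#' @param iid_duration,id_duration `c(min, max)` uniform event durations (s).
#'   IID support must lie strictly below the ID cutoff and ID support
#'   strictly above it.
#' @param amplitude Named numeric: peak amplitude (uV) per region label the
#'   origin's discharges are expressed on.
#' @param edges `NULL` or data.frame(from, to, delay_s) of propagation edges
#'   between region nodes ("CA3ab" denotes the CA3a+CA3b pacemaker node).
#' @return A list of class `origin_spec`.
#' @export
origin_spec <- function(initiation_electrode,
                        latency_iid, latency_id,
                        n_iid = list(shift = 2, size = 18,
                                     prob = (8.19 - 2) / 18),
                        resting = list(min = 113, range = 504 - 113,
                                       shape1 = 2,
                                       shape2 = 2 * (1 - (241.23 - 113) / (504 - 113)) /
                                                    ((241.23 - 113) / (504 - 113))),
                        iid_gap = c(5, 10),
                        iid_duration, id_duration,
                        amplitude, edges = NULL) {
  structure(list(initiation_electrode = initiation_electrode,
                 latency_iid = latency_iid, latency_id = latency_id,
                 n_iid = n_iid, resting = resting, iid_gap = iid_gap,
                 iid_duration = iid_duration, id_duration = id_duration,
                 amplitude = amplitude, edges = edges),
            class = "origin_spec")
}

#' Default two-origin specification (low-Mg2+ scenario)
#'
#' CA3 origin: pacemaker at electrode "27" (CA3b), anterograde edges
#' CA3ab -> CA1 -> Sub and retrograde edges CA3ab -> CA3c -> DG; amplitudes
#' largest in CA3. Sub origin: pacemaker at "83", expressed on subicular
#' electrodes only, smaller amplitude than CA3-origin activity in CA3, longer
#' IIDs and shorter IDs than the CA3 origin.
#'
#' @return Named list of two [origin_spec()]s.
#' @export
default_origins <- function() {
  list(
    CA3 = origin_spec(
      initiation_electrode = "27",
      latency_iid = c(180, 290), latency_id = c(230, 1840),
      iid_duration = c(0.3, 1.0), id_duration = c(10, 25),
      amplitude = c(CA3a = 280, CA3b = 300, CA3c = 200,
                    CA1 = 220, Sub = 150, DG = 180),
      edges = data.frame(
        from = c("CA3ab", "CA1", "CA3ab", "CA3c"),
        to = c("CA1", "Sub", "CA3c", "DG"),
        delay_s = c(0.015, 0.015, 0.015, 0.010),
        stringsAsFactors = FALSE)),
    Sub = origin_spec(
      initiation_electrode = "83",
      latency_iid = c(190, 250), latency_id = c(280, 1540),
      iid_duration = c(0.8, 2.0), id_duration = c(5.5, 10),
      amplitude = c(Sub = 180),
      edges = NULL)
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$duration_s <= 0 || cfg$sample_rate <= 0)
    stop("duration_s and sample_rate must be positive")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  for (nm in names(cfg$origins)) {
    o <- cfg$origins[[nm]]
    if (max(o$iid_duration) >= cfg$id_cutoff_s)
      stop("origin ", nm, ": IID duration support must lie strictly below the ",
           "ID cutoff (", cfg$id_cutoff_s, " s)")
    if (min(o$id_duration) <= cfg$id_cutoff_s)
      stop("origin ", nm, ": ID duration support must lie strictly above the ",
           "ID cutoff (", cfg$id_cutoff_s, " s)")
    if (!is.null(o$edges)) {
      if (any(o$edges$delay_s < 0)) stop("origin ", nm, ": negative edge delay")
      if (any(o$edges$from == "Sub" & o$edges$to == "CA1"))
        stop("origin ", nm, ": Sub -> CA1 edge is not allowed ",
             "(no backward propagation)")
    }
  }
  if (!is.null(cfg$origins$CA3)) {
    e <- cfg$origins$CA3$edges
    need <- c("CA3ab>CA1", "CA1>Sub", "CA3ab>CA3c", "CA3c>DG")
    have <- paste0(e$from, ">", e$to)
    if (!all(need %in% have))
      stop("CA3 origin must cover edges ", paste(need, collapse = ", "))
  }
  if (!is.null(cfg$origins$Sub) && !is.null(cfg$origins$Sub$edges) &&
      nrow(cfg$origins$Sub$edges) > 0)
    stop("Sub origin propagates within the subiculum only (no edges)")
  # static feasibility: the first full cycle of every origin must fit
  min_needed <- max(vapply(cfg$origins, function(o)
    max(o$latency_id) + max(o$id_duration) + 1, 0))
  if (cfg$duration_s < min_needed)
    stop("duration_s too short for one full discharge cycle; ",
         "increase to at least ", ceiling(min_needed), " s ",
         "(first-ID latency upper bound plus the longest ID)")
  invisible(cfg)
}

#' Configured mean of the per-cycle IID count / resting period
#'
#' Closed-form means of the generator's distributions, used as the reference
#' in recovery tests.
#' @param cfg A [sim_config()].
#' @name config_means
#' @export
config_mean_n_iid <- function(cfg) {
  m <- vapply(cfg$origins, function(o) o$n_iid$shift + o$n_iid$size * o$n_iid$prob, 0)
  mean(m)
}

#' @rdname config_means
#' @export
config_mean_resting <- function(cfg) {
  m <- vapply(cfg$origins, function(o)
    o$resting$min + o$resting$range * o$resting$shape1 /
      (o$resting$shape1 + o$resting$shape2), 0)
  mean(m)
}

#' Low-Mg2+ / high-K+ scenario configurations
#'
#' Convenience constructors with the default two-origin structure. The two
#' perfusion models share the discharge phenomenology; they differ in which
#' pharmacological agents are applied on top (see [add_drug_epoch()]).
#'
#' @inheritParams sim_config
#' @name scenarios
#' @export
sim_config_low_mg <- function(seed = 1, duration_s = 3000, sample_rate = 20000,
                              noise_sd = 10) {
  sim_config(seed = seed, duration_s = duration_s, sample_rate = sample_rate,
             noise_sd = noise_sd)
}

#' @rdname scenarios
#' @export
sim_config_high_k <- function(seed = 1, duration_s = 3000, sample_rate = 20000,
                              noise_sd = 10) {
  sim_config(seed = seed, duration_s = duration_s, sample_rate = sample_rate,
             noise_sd = noise_sd)
}

#' Annotate a drug epoch with origin/class-specific rate modulation
#'
#' @param cfg A [sim_config()].
#' @param label Epoch label (e.g. "bumetanide").
#' @param start_s,end_s Epoch bounds in seconds.
#' @param modulation Named numeric multipliers in `[0, 1]` keyed
#'   `"<origin>.<class>"`; 0 abolishes, 1 leaves the rate unchanged.
#' @param agent Perfusate / drug name recorded in the annotation.
#' @return The updated config.
#' @export
add_drug_epoch <- function(cfg, label, start_s, end_s,
                           modulation = c(CA3.IID = 1, CA3.ID = 1,
                                          Sub.IID = 1, Sub.ID = 1),
                           agent = label) {
  if (any(modulation < 0 | modulation > 1))
    stop("modulation multipliers must lie in [0, 1]")
  ep <- data.frame(label = label, start_s = start_s, end_s = end_s,
                   agent = agent, stringsAsFactors = FALSE)
  cfg$drug_epochs <- validate_epochs(rbind(cfg$drug_epochs, ep))
  cfg$modulation[[label]] <- modulation
  validate_sim_config(cfg)
  cfg
}

with_sim_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

runif1 <- function(rng) stats::runif(1, rng[1], rng[2])

# Draw the network-level discharge schedule for one origin.
# Returns data.frame(origin, cycle, class, onset_s, duration_s) plus
# cycle-level truth in attr "cycles".
draw_origin_schedule <- function(o, origin, duration_s, id_cutoff_s) {
  rows <- list(); cyc <- list()
  t_first <- runif1(o$latency_iid)
  t_first_id <- runif1(o$latency_id)
  if (t_first_id <= t_first + 2) t_first_id <- t_first + 2
  k <- 0L
  cycle_first_onset <- t_first
  repeat {
    k <- k + 1L
    n <- o$n_iid$shift + stats::rbinom(1, o$n_iid$size, o$n_iid$prob)
    iid_dur <- stats::runif(n, o$iid_duration[1], o$iid_duration[2])
    if (k == 1L) {
      # stretch the first train so the drawn first-ID latency is honoured
      id_onset <- t_first_id
      gaps <- rep((id_onset - cycle_first_onset) / n, n)
    } else {
      gaps <- stats::runif(n, o$iid_gap[1], o$iid_gap[2])
      id_onset <- cycle_first_onset + sum(gaps)
    }
    iid_onsets <- cycle_first_onset + c(0, cumsum(gaps))[seq_len(n)]
    id_dur <- runif1(o$id_duration)
    resting <- o$resting$min +
      o$resting$range * stats::rbeta(1, o$resting$shape1, o$resting$shape2)
    if (cycle_first_onset >= duration_s) break
    rows[[length(rows) + 1L]] <- data.frame(
      origin = origin, cycle = k,
      class = c(rep("IID", n), "ID"),
      onset_s = c(iid_onsets, id_onset),
      duration_s = c(iid_dur, id_dur),
      stringsAsFactors = FALSE)
    cyc[[length(cyc) + 1L]] <- data.frame(
      origin = origin, cycle = k, n_iids = n,
      first_onset_s = cycle_first_onset,
      id_onset_s = id_onset, id_offset_s = id_onset + id_dur,
      resting_s = resting, stringsAsFactors = FALSE)
    cycle_first_onset <- id_onset + id_dur + resting
    if (cycle_first_onset >= duration_s) break
  }
  sched <- do.call(rbind, rows)
  if (is.null(sched)) sched <- data.frame(origin = character(), cycle = integer(),
                                          class = character(), onset_s = numeric(),
                                          duration_s = numeric())
  # clip events beyond the recording; truncate an event running over the end
  keep <- sched$onset_s < duration_s - 0.5
  sched <- sched[keep, , drop = FALSE]
  over <- sched$onset_s + sched$duration_s > duration_s
  sched$duration_s[over] <- duration_s - sched$onset_s[over]
  sched$class <- ifelse(sched$duration_s > id_cutoff_s, "ID", "IID")
  cycles <- do.call(rbind, cyc)
  if (!is.null(cycles)) {
    cycles$complete <- cycles$id_offset_s <= duration_s &
      vapply(seq_len(nrow(cycles)), function(i)
        any(sched$cycle == cycles$cycle[i] & sched$class == "ID"), TRUE)
  }
  attr(sched, "cycles") <- cycles
  sched
}

# Cumulative per-electrode delay/amplitude table for one origin.
origin_electrode_table <- function(o, layout, regions, speed_um_per_s) {
  node_members <- function(node) {
    labs <- if (node == "CA3ab") c("CA3a", "CA3b") else node
    names(regions$assignment)[regions$assignment %in% labs]
  }
  init <- o$initiation_electrode
  init_region <- electrode_region(regions, init)
  root <- if (init_region %in% c("CA3a", "CA3b")) "CA3ab" else init_region
  entry <- stats::setNames(init, root)
  cum <- stats::setNames(0, root)
  if (!is.null(o$edges)) {
    remaining <- o$edges
    while (nrow(remaining)) {
      ready <- remaining$from %in% names(cum)
      if (!any(ready)) stop("propagation edges do not form a path from the origin")
      for (i in which(ready)) {
        from <- remaining$from[i]; to <- remaining$to[i]
        mem <- node_members(to)
        if (!length(mem)) stop("no electrodes labelled for region node ", to)
        d <- vapply(mem, function(e) electrode_distance(layout, e, entry[[from]]), 0)
        entry[[to]] <- mem[which.min(d)]
        cum[[to]] <- cum[[from]] + remaining$delay_s[i]
      }
      remaining <- remaining[!ready, , drop = FALSE]
    }
  }
  tabs <- lapply(names(cum), function(node) {
    mem <- node_members(node)
    amp <- o$amplitude[electrode_region(regions, mem)]
    keep <- !is.na(amp)
    mem <- mem[keep]
    data.frame(
      electrode_id = mem,
      region = electrode_region(regions, mem),
      delay_s = cum[[node]] + vapply(mem, function(e)
        electrode_distance(layout, e, entry[[node]]), 0) / speed_um_per_s,
      amplitude = as.numeric(amp[keep]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, tabs)
}

# Area-balanced spike-wave core shared by both templates: a sharp negative
# lobe followed by a compact positive rebound that exactly cancels its area.
# Both lobes sit inside the 1-100 Hz analysis band; anything slower or
# unbalanced would acquire large symmetric compensation shoulders under the
# zero-phase 1 Hz high-pass and smear the detected onset backwards in time.
spike_wave <- function(t, amp, w1, w2) {
  y <- numeric(length(t))
  neg <- t < w1
  y[neg] <- -amp * sin(pi * t[neg] / w1)
  reb <- t >= w1 & t < w1 + w2
  y[reb] <- (amp * w1 / w2) * sin(pi * (t[reb] - w1) / w2)
  y
}

# IID transient: spike-wave onset plus a tapered in-band (7 Hz) afterburst
# carrying the remainder of the event duration.
iid_waveform <- function(d, amp, fs) {
  n <- max(2L, round(d * fs))
  t <- seq_len(n) / fs   # first stored sample is already non-zero
  w1 <- min(0.04, 0.4 * d)
  w2 <- min(0.06, 0.6 * (d - w1))
  y <- spike_wave(t, amp, w1, w2)
  fill <- t >= w1 + w2
  if (any(fill)) {
    tf <- t[fill] - (w1 + w2)
    W <- d - (w1 + w2)
    y[fill] <- y[fill] + 0.3 * amp * sin(pi * tf / W) * sin(2 * pi * 7 * tf)
  }
  y
}

# Ictal-like waveform: spike-wave onset followed by a sustained 8 Hz
# tonic-clonic-like oscillatory burst with attack/release envelope (the
# burst carrier is zero-mean, so the composite stays area-balanced).
id_waveform <- function(d, amp, fs) {
  n <- max(2L, round(d * fs))
  t <- seq_len(n) / fs   # first stored sample is already non-zero
  y <- spike_wave(t, amp, 0.04, 0.06)
  env <- pmin(1, t / 0.2) * pmin(1, pmax(0, (d - t) / 1.0))
  y + -0.8 * amp * env * sin(2 * pi * 8 * t)
}

#' Simulate a synthetic slice recording with ground truth
#'
#' Draws discharge-cycle schedules for each origin, expands them over the
#' electrode grid via the origin's propagation structure, synthesises
#' waveforms, applies drug-epoch rate modulation by thinning, and adds
#' i.i.d. Gaussian noise. The same config (including seed) yields
#' bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @param layout An [mea_layout()].
#' @param regions A [region_map()]; defaults to the bundled fixture map.
#' @return A list of class `mea_simulation`: `recording`
#'   (an [new_recording()]), `truth` (one row per discharge x electrode:
#'   discharge_id, origin, class, cycle, electrode_id, region, onset_s,
#'   duration_s, epoch), and `cycles` (cycle-level truth with resting
#'   periods).
#' @export
simulate_recording <- function(cfg, layout = mea_layout(),
                               regions = default_region_map(layout)) {
  validate_sim_config(cfg)
  with_sim_seed(cfg$seed, {
    scheds <- lapply(names(cfg$origins), function(nm)
      draw_origin_schedule(cfg$origins[[nm]], nm, cfg$duration_s, cfg$id_cutoff_s))
    names(scheds) <- names(cfg$origins)
    cycles <- do.call(rbind, lapply(scheds, attr, "cycles"))
    sched <- do.call(rbind, scheds)
    rownames(sched) <- NULL
    # epoch label + thinning
    sched$epoch <- NA_character_
    sched$keep <- TRUE
    if (!is.null(cfg$drug_epochs)) {
      for (i in seq_len(nrow(cfg$drug_epochs))) {
        ep <- cfg$drug_epochs[i, ]
        in_ep <- sched$onset_s >= ep$start_s & sched$onset_s < ep$end_s
        sched$epoch[in_ep] <- ep$label
        mod <- cfg$modulation[[ep$label]]
        if (!is.null(mod)) {
          key <- paste(sched$origin, sched$class, sep = ".")
          mult <- ifelse(key %in% names(mod), mod[key], 1)
          u <- stats::runif(nrow(sched))
          sched$keep[in_ep] <- sched$keep[in_ep] &
            (mult[in_ep] > 0 & u[in_ep] <= mult[in_ep])
        }
      }
    }
    kept <- sched[sched$keep, , drop = FALSE]
    # expand over electrodes
    etabs <- lapply(names(cfg$origins), function(nm)
      origin_electrode_table(cfg$origins[[nm]], layout, regions, cfg$speed_um_per_s))
    names(etabs) <- names(cfg$origins)
    truth_rows <- vector("list", nrow(kept))
    for (i in seq_len(nrow(kept))) {
      et <- etabs[[kept$origin[i]]]
      truth_rows[[i]] <- data.frame(
        discharge_id = sprintf("%s_c%02d_%s_%03d", kept$origin[i], kept$cycle[i],
                               kept$class[i], i),
        origin = kept$origin[i], class = kept$class[i], cycle = kept$cycle[i],
        electrode_id = et$electrode_id, region = et$region,
        onset_s = kept$onset_s[i] + et$delay_s,
        duration_s = kept$duration_s[i],
        amplitude_uV = et$amplitude,
        epoch = kept$epoch[i],
        stringsAsFactors = FALSE)
    }
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(discharge_id = character(), origin = character(),
                 class = character(), cycle = integer(),
                 electrode_id = character(), region = character(),
                 onset_s = numeric(), duration_s = numeric(),
                 amplitude_uV = numeric(), epoch = character())
    rownames(truth) <- NULL
    # synthesise
    fs <- cfg$sample_rate
    n <- round(cfg$duration_s * fs)
    chan <- layout$electrode_id
    dat <- matrix(0, nrow = length(chan), ncol = n)
    ch_index <- stats::setNames(seq_along(chan), chan)
    for (i in seq_len(nrow(truth))) {
      w <- if (truth$class[i] == "ID")
        id_waveform(truth$duration_s[i], truth$amplitude_uV[i], fs)
      else iid_waveform(truth$duration_s[i], truth$amplitude_uV[i], fs)
      i0 <- as.integer(round(truth$onset_s[i] * fs)) + 1L
      i1 <- min(n, i0 + length(w) - 1L)
      if (i0 > n) next
      r <- ch_index[[truth$electrode_id[i]]]
      dat[r, i0:i1] <- dat[r, i0:i1] + w[seq_len(i1 - i0 + 1L)]
    }
    if (cfg$noise_sd > 0)
      for (r in seq_along(chan))
        dat[r, ] <- dat[r, ] + stats::rnorm(n, 0, cfg$noise_sd)
    rec <- new_recording(dat, fs, chan, epochs = cfg$drug_epochs)
    structure(list(recording = rec, truth = truth, cycles = cycles,
                   config = cfg),
              class = "mea_simulation")
  })
}

#' @export
print.mea_simulation <- function(x, ...) {
  cat("Synthetic slice recording\n")
  print(x$recording)
  nd <- length(unique(x$truth$discharge_id))
  cat(sprintf("Ground truth: %d discharges (%d IID, %d ID) over %d cycles\n",
              nd,
              length(unique(x$truth$discharge_id[x$truth$class == "IID"])),
              length(unique(x$truth$discharge_id[x$truth$class == "ID"])),
              if (is.null(x$cycles)) 0L else nrow(x$cycles)))
  invisible(x)
}
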
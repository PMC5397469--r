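# shared fixtures: small, fast simulation configs and signal generators

quick_origins <- function() {
  org <- default_origins()
  org$CA3$latency_iid <- c(2, 3)
  org$CA3$latency_id <- c(30, 40)
  org$CA3$id_duration <- c(6, 8)
  org$Sub$latency_iid <- c(4, 5)
  org$Sub$latency_id <- c(45, 55)
  org$Sub$id_duration <- c(5.5, 6.5)
  # fewer IIDs per cycle (mean 5) so that the stretched first-cycle trains
  # keep events well separated at these compressed latencies
  org$CA3$n_iid <- org$Sub$n_iid <- list(shift = 2, size = 6, prob = 0.5)
  org
}

quick_config <- function(seed = 1, duration_s = 90, sample_rate = 500,
                         noise_sd = 5) {
  sim_config(seed = seed, duration_s = duration_s, sample_rate = sample_rate,
             noise_sd = noise_sd, origins = quick_origins())
}

fp500 <- function() pipeline_config(preprocess = fp_params(c(1, 100), 500))

# band-limited noise trace like the pipeline's field potentials
filtered_noise <- function(n, fs = 500, sd = 10, seed = 1) {
  set.seed(seed)
  bf <- signal::butter(4, c(1, 100) / (fs / 2), type = "pass")
  zp_filtfilt(bf$b, bf$a, stats::rnorm(n, 0, sd))
}

manual_baseline <- function(mean = 0, sd = 1) {
  structure(list(mean = mean, sd = sd, start_s = 0, end_s = 0.5),
            class = "baseline_stats")
}

# synthetic per-electrode event table (detector output shape)
make_events <- function(electrode_id, onset_s, duration_s = 0.5,
                        peak = 100) {
  data.frame(electrode_id = as.character(electrode_id), onset_s = onset_s,
             offset_s = onset_s + duration_s,
             duration_s = rep_len(duration_s, length(electrode_id)),
             peak_amplitude_uV = rep_len(peak, length(electrode_id)),
             peak_time_s = onset_s + duration_s / 2,
             polarity = rep_len("negative", length(electrode_id)),
             stringsAsFactors = FALSE)
}
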
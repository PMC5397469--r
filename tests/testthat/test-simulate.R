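test_that("identical configs give bit-identical recordings and truth", {
  s1 <- simulate_recording(quick_config(seed = 5, duration_s = 70))
  s2 <- simulate_recording(quick_config(seed = 5, duration_s = 70))
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$cycles, s2$cycles)
  s3 <- simulate_recording(quick_config(seed = 6, duration_s = 70))
  expect_false(identical(s1$recording$data, s3$recording$data))
})

test_that("propagation delays are additive along the CA3 -> CA1 -> Sub path", {
  sim <- simulate_recording(quick_config(seed = 7, noise_sd = 0))
  tr <- sim$truth
  d1 <- tr[tr$discharge_id == tr$discharge_id[1], ]
  t_init <- min(d1$onset_s)
  expect_equal(d1$electrode_id[which.min(d1$onset_s)], "27")
  # entry electrodes carry exactly the cumulative edge delays
  sub_entry <- min(d1$onset_s[d1$region == "Sub"])
  ca1_entry <- min(d1$onset_s[d1$region == "CA1"])
  expect_equal(ca1_entry - t_init, 0.015, tolerance = 1e-9)
  expect_equal(sub_entry - t_init, 0.030, tolerance = 1e-9)
  # within a CA3-origin discharge, CA3a/b leads every other region
  ca3_max <- max(d1$onset_s[d1$region %in% c("CA3a", "CA3b")])
  expect_true(all(d1$onset_s[!(d1$region %in% c("CA3a", "CA3b"))] >= ca3_max - 1e-9))
})

test_that("Sub-origin discharges are expressed on subicular electrodes only", {
  sim <- simulate_recording(quick_config(seed = 7, noise_sd = 0))
  tr <- sim$truth[sim$truth$origin == "Sub", ]
  expect_gt(nrow(tr), 0)
  expect_setequal(unique(tr$region), "Sub")
})

test_that("each generated cycle contains exactly one ID", {
  sim <- simulate_recording(quick_config(seed = 8, duration_s = 120))
  tr <- sim$truth
  per_cycle <- table(tr$origin[tr$class == "ID"], tr$cycle[tr$class == "ID"])
  # per discharge x electrode rows: count unique ID discharges per cycle
  ids <- unique(tr[tr$class == "ID", c("origin", "cycle", "discharge_id")])
  expect_true(all(table(ids$origin, ids$cycle) <= 1))
  cyc <- sim$cycles[sim$cycles$complete, ]
  expect_true(all(cyc$n_iids >= 2 & cyc$n_iids <= 20))
})

test_that("rate modulation 0 abolishes the targeted class within the epoch", {
  cfg <- quick_config(seed = 9, duration_s = 120)
  cfg <- add_drug_epoch(cfg, "d-AP5", 10, 120,
                        modulation = c(Sub.ID = 0, Sub.IID = 1,
                                       CA3.ID = 1, CA3.IID = 1))
  sim <- simulate_recording(cfg)
  tr <- sim$truth
  in_ep <- tr$onset_s >= 10 & tr$onset_s < 120
  expect_equal(sum(tr$origin == "Sub" & tr$class == "ID" & in_ep), 0)
  expect_gt(sum(tr$origin == "CA3" & tr$class == "ID" & in_ep), 0)
})

test_that("per-cycle IID counts match the configured distribution mean", {
  # schedule-level property at >= 200 cycles: cheap, no waveform synthesis
  o <- quick_origins()$CA3
  set.seed(99)
  counts <- c()
  while (length(counts) < 220) {
    sched <- ictomap:::draw_origin_schedule(o, "CA3", 4000, 5)
    cyc <- attr(sched, "cycles")
    counts <- c(counts, cyc$n_iids[cyc$complete])
  }
  m <- o$n_iid$shift + o$n_iid$size * o$n_iid$prob
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - m), 3 * se)
  expect_true(all(counts >= 2 & counts <= 20))
})

test_that("with zero noise the first departure from zero matches truth", {
  sim <- simulate_recording(quick_config(seed = 10, duration_s = 70,
                                         noise_sd = 0))
  raw <- sim$recording$data
  fs <- sim$recording$sample_rate
  tr <- sim$truth
  for (el in unique(tr$electrode_id)[1:10]) {
    first_true <- min(tr$onset_s[tr$electrode_id == el])
    ch <- match(el, sim$recording$channels)
    first_dep <- (which(raw[ch, ] != 0)[1] - 1) / fs
    expect_lt(abs(first_dep - first_true), 1 / fs + 1e-9)
  }
})

test_that("configuration invariants are enforced", {
  org <- quick_origins()
  org$CA3$iid_duration <- c(0.3, 6)   # IID support must stay below the cutoff
  expect_error(sim_config(origins = org, duration_s = 100), "cutoff")
  org <- quick_origins()
  org$Sub$edges <- data.frame(from = "Sub", to = "CA1", delay_s = 0.01)
  expect_error(sim_config(origins = org, duration_s = 100), "backward|Sub")
  org <- quick_origins()
  org$CA3$edges$delay_s[1] <- -0.01
  expect_error(sim_config(origins = org, duration_s = 100), "negative")
  expect_error(sim_config(origins = quick_origins(), duration_s = 10),
               "duration_s too short")
})

test_that("simulated recordings carry the drug-epoch annotations", {
  cfg <- quick_config(seed = 11, duration_s = 100)
  cfg <- add_drug_epoch(cfg, "control", 0, 50, agent = "low-Mg2+ ACSF")
  cfg <- add_drug_epoch(cfg, "bumetanide", 50, 100)
  sim <- simulate_recording(cfg)
  expect_equal(sim$recording$epochs$label, c("control", "bumetanide"))
})
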
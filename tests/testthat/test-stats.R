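synthetic_ds <- function() {
  # two CA3-origin IIDs and one Sub-origin ID with known pair amplitudes
  members <- rbind(
    make_events(c("17", "27", "41"), c(10.00, 10.00, 10.02), peak = c(100, 120, 80)),
    make_events(c("17", "27"), c(100.00, 100.00), peak = c(110, 130)),
    make_events(c("72", "82", "83"), c(300, 300, 300), 6, peak = c(60, 70, 90)))
  members$discharge_id <- rep(c("d001", "d002", "d003"), c(3, 2, 3))
  discharges <- data.frame(
    discharge_id = c("d001", "d002", "d003"),
    network_onset_s = c(10, 100, 300), n_electrodes = c(3, 2, 3),
    initiation_electrode = c("27", "27", "83"),
    initiation_region = c("CA3b", "CA3b", "Sub"),
    origin = c("CA3", "CA3", "Sub"),
    discharge_class = c("IID", "IID", "ID"),
    duration_s = c(0.5, 0.5, 6), offset_s = c(10.5, 100.5, 306),
    participating_regions = "", conflict = FALSE, stringsAsFactors = FALSE)
  structure(list(discharges = discharges, members = members),
            class = "discharge_set")
}

test_that("region parameters average the designated electrode pair", {
  rp <- region_parameters(synthetic_ds(), default_region_map(),
                          duration_s = 600)
  ca3 <- rp[rp$region == "CA3" & rp$origin == "CA3" & rp$class == "IID", ]
  expect_equal(ca3$n, 2)
  expect_equal(ca3$mean_amplitude_uV, mean(c(mean(c(100, 120)),
                                             mean(c(110, 130)))))
  expect_equal(ca3$frequency_per_min, 2 / 10)
  sub <- rp[rp$region == "Sub" & rp$origin == "Sub" & rp$class == "ID", ]
  expect_equal(sub$n, 1)
  expect_equal(sub$mean_amplitude_uV, mean(c(60, 70)))  # pair is 72/82
  # CA1 pair saw only one electrode of d001
  ca1 <- rp[rp$region == "CA1" & rp$origin == "CA3" & rp$class == "IID", ]
  expect_equal(ca1$n, 1)
  expect_equal(ca1$n_pair_incomplete, 1)
})

test_that("frequencies scale inversely with epoch duration", {
  ds <- synthetic_ds()
  rp10 <- region_parameters(ds, default_region_map(), duration_s = 600)
  rp20 <- region_parameters(ds, default_region_map(), duration_s = 1200)
  expect_equal(rp10$frequency_per_min, 2 * rp20$frequency_per_min)
})

test_that("region parameters require designated pairs", {
  rm <- region_map(c("27" = "CA3b"), layout = mea_layout())
  expect_error(region_parameters(synthetic_ds(), rm, duration_s = 10),
               "pairs")
})

test_that("simulation recovers the configured amplitude ordering", {
  sim <- simulate_recording(quick_config(seed = 71, duration_s = 150))
  rep <- run_pipeline(sim$recording, default_region_map(), fp500(),
                      verbose = FALSE)
  rp <- rep$region_params
  ca3 <- rp[rp$region == "CA3" & rp$origin == "CA3", ]
  sub <- rp[rp$region == "Sub" & rp$origin == "Sub", ]
  expect_gt(min(ca3$mean_amplitude_uV, na.rm = TRUE),
            max(sub$mean_amplitude_uV, na.rm = TRUE))
})

test_that("paired t-test matches the hand-computed statistic", {
  a <- c(1, 2, 3); b <- c(2, 4, 3.5)
  res <- compare_epochs(list(a, b), design = "paired")
  d <- a - b
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(3)))
  expect_equal(res$df, 2)
  expect_equal(res$test, "paired-t")
  # antisymmetry under sample swap
  res2 <- compare_epochs(list(b, a), design = "paired")
  expect_equal(res2$statistic, -res$statistic)
  expect_equal(res2$p_value, res$p_value)
})

test_that("identical paired samples give t = 0 and p = 1", {
  res <- compare_epochs(list(c(1, 2, 3), c(1, 2, 3)), design = "paired")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("one-way ANOVA on identical groups gives F = 0", {
  g <- c(1, 2, 3, 4)
  res <- compare_epochs(list(g, g, g), design = "anova")
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 2)
  expect_equal(res$df2, 9)
  # cross-check against aov on distinct groups
  set.seed(81)
  gs <- list(rnorm(6), rnorm(6, 1), rnorm(6, 2))
  res2 <- compare_epochs(gs, design = "anova")
  fit <- summary(stats::aov(unlist(gs) ~ factor(rep(1:3, each = 6))))[[1]]
  expect_equal(res2$statistic, fit$`F value`[1])
  expect_equal(res2$p_value, fit$`Pr(>F)`[1])
})

test_that("epoch comparison rejects undersized designs", {
  expect_error(compare_epochs(list(1, 1), design = "paired"), "at least 2")
  expect_error(compare_epochs(list(c(1, 2)), design = "anova"), ">= 2")
  expect_error(compare_epochs(list(c(1, 2), c(1, 2), 3), design = "anova"),
               "at least 2")
})

test_that("densitometry normalisation follows the loading-control rule", {
  tab <- rbind(
    data.frame(animal = 1, region = "HP",
               protein = c("beta-actin", "NKCC1"), intensity = c(1000, 500)),
    data.frame(animal = 1, region = "Sub",
               protein = c("beta-actin", "NKCC1"), intensity = c(800, 200)),
    data.frame(animal = 2, region = "HP",
               protein = c("beta-actin", "NKCC1"), intensity = c(900, 450)),
    data.frame(animal = 2, region = "Sub",
               protein = c("beta-actin", "NKCC1"), intensity = c(1100, 275)))
  out <- normalize_densitometry(tab)
  expect_equal(out$normalized$HP, c(1, 1))
  expect_equal(out$normalized$Sub, c((200 / 800) / (500 / 1000),
                                     (275 / 1100) / (450 / 900)))
  expect_equal(out$tests$protein, "NKCC1")
})

test_that("identical intensities in both regions normalise to 1 with t = 0", {
  tab <- expand.grid(animal = 1:3, region = c("HP", "Sub"),
                     protein = c("beta-actin", "NKCC1"),
                     stringsAsFactors = FALSE)
  tab$intensity <- rep(c(1000, 400), each = 6)
  out <- normalize_densitometry(tab)
  expect_true(all(out$normalized$Sub == 1))
  expect_equal(out$tests$statistic, 0)
  expect_equal(out$tests$p_value, 1)
})

test_that("densitometry validation rejects bad tables", {
  tab <- data.frame(animal = 1, region = "HP", protein = "beta-actin",
                    intensity = -1)
  expect_error(normalize_densitometry(tab), "positive")
  tab2 <- data.frame(animal = 1, region = "HP", protein = "beta-actin",
                     intensity = 10)
  expect_error(normalize_densitometry(tab2), "target")
  tab3 <- rbind(data.frame(animal = 1, region = "HP",
                           protein = c("beta-actin", "NKCC1"),
                           intensity = c(10, 5)))
  expect_error(normalize_densitometry(tab3), "Sub")
})

test_that("a simulated 8-animal NKCC1 deficit in Sub is detected", {
  tab <- simulate_densitometry(n_animals = 8,
                               effects = c(NKCC1 = 0.55, NR2A = 1.9,
                                           NR2B = 1.75), seed = 7)
  out <- normalize_densitometry(tab)
  tn <- out$tests[out$tests$protein == "NKCC1", ]
  expect_true(tn$significant)
  expect_gt(tn$statistic, 0)           # HP > Sub
  expect_lt(mean(out$normalized$Sub[out$normalized$protein == "NKCC1"]), 1)
  t2 <- out$tests[out$tests$protein == "NR2A", ]
  expect_lt(t2$statistic, 0)           # HP < Sub
  expect_true(t2$significant)
})
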
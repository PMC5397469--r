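#!/usr/bin/env Rscript

# Western-blot densitometry workflow on a synthetic 8-animal table
# (generated, not measured): relative levels as target / beta-actin,
# subiculum normalised to hippocampus proper (HP = 1.0), paired t-tests
# across animals. The synthetic effects follow the qualitative pattern of
# the electrophysiology: NKCC1 lower in Sub, NR2A/NR2B higher in Sub.

library(ictomap)

dir.create("results", showWarnings = FALSE)

tab <- simulate_densitometry(n_animals = 8,
                             effects = c(NKCC1 = 0.55, NR2A = 1.9,
                                         NR2B = 1.75),
                             seed = 1)
write.csv(tab, "results/densitometry_intensities.csv", row.names = FALSE)

out <- normalize_densitometry(tab)
write.csv(out$normalized, "results/densitometry_normalized.csv",
          row.names = FALSE)
write.csv(out$tests, "results/densitometry_tests.csv", row.names = FALSE)

for (i in seq_len(nrow(out$tests))) {
  tt <- out$tests[i, ]
  mn <- mean(out$normalized$Sub[out$normalized$protein == tt$protein])
  message(sprintf(
    "%-6s Sub/HP = %.2f; paired t(%d) = %.2f, p = %.4f%s (raw p-value)",
    tt$protein, mn, tt$df, tt$statistic, tt$p_value,
    if (tt$significant) " *" else ""))
}
message("tables in results/densitometry_*.csv")
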
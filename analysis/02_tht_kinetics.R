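#!/usr/bin/env Rscript

# Step 2: fit every well of the simulated ThT plates to the Boltzmann
# sigmoid, derive elongation rates and lag times, compare fits against the
# generator's truth, and compute per-condition percent protection.

suppressPackageStartupMessages(library(aggkinetics))

data_dir <- "results/data"
stopifnot(dir.exists(data_dir))  # run analysis/01_simulate_datasets.R first

plates <- list.files(data_dir, pattern = "^tht_.*\\.csv$", full.names = TRUE)
plates <- plates[!grepl("truth", plates)]

fits <- NULL
for (f in plates) {
  cn <- sub("^tht_(.*)\\.csv$", "\\1", basename(f))
  res <- analyze_plate(read_plate_kinetics(f))
  res$condition <- cn
  fits <- rbind(fits, res)
}
write.csv(fits, "results/tht_fits.csv", row.names = FALSE)

truth <- read.csv(file.path(data_dir, "tht_truth.csv"))
m <- merge(fits, truth, by = c("well_id", "condition"),
           suffixes = c("_fit", "_true"))
agg_wells <- m[m$aggregating & m$converged, ]
cat(sprintf("fitted %d wells (%d aggregating & converged)\n",
            nrow(m), nrow(agg_wells)))
cat(sprintf("median |t50 error|: %.2f%%\n",
            100 * median(abs(agg_wells$t50_s_fit - agg_wells$t50_s_true) /
                           agg_wells$t50_s_true)))

prot <- protection_table(fits, reference = "alone")
write.csv(prot, "results/tht_protection.csv", row.names = FALSE)
cat("\npercent protection (vs substrate alone):\n")
print(prot[order(-prot$percent_protection),
           c("condition", "percent_protection", "n")], row.names = FALSE)

rates <- aggregate(elongation_rate ~ condition, fits, mean, na.rm = TRUE)
write.csv(rates, "results/tht_elongation_rates.csv", row.names = FALSE)
cat("\nmean elongation rate (a.u./s) by condition:\n")
print(rates, row.names = FALSE)
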
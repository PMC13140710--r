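#!/usr/bin/env Rscript

# Step 1: simulate every raw dataset the downstream analyses consume and
# write them to disk in the same plain-text formats a plate reader,
# microscope export or photon-counting acquisition would produce, together
# with their ground-truth tables. Later steps read these files back through
# the package's parsers, so the whole pipeline is exercised end to end.
#
# Study design (mirrors a chaperone titration on an aggregating
# low-complexity domain): a substrate-alone condition, an inert protein
# control, and two chaperones of different potency at an equimolar ratio.
# The long-assay timescale (742 cycles of 350 s, ~72 h; lags of ~10 h) is
# the regime in which per-well event coding is meaningful.

suppressPackageStartupMessages(library(aggkinetics))

seed <- 20260925L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

horizon <- 742 * 350  # s

conditions <- list(
  # condition              Ff  midpoint  censored frac
  "alone"      = list(Ff = 1100, t50 = 36000, frac = 0.00),
  "bsa_1to1"   = list(Ff = 1050, t50 = 38000, frac = 0.00),
  "hspb1_1to1" = list(Ff = 500,  t50 = 72000, frac = 0.25),
  "hspb5_1to1" = list(Ff = 220,  t50 = 110000, frac = 0.60))

truth_all <- NULL
for (i in seq_along(conditions)) {
  cn <- names(conditions)[i]
  p <- conditions[[i]]
  truth <- tht_truth(Fi = 100, Ff = p$Ff, t50_s = p$t50, k_s = 2000,
                     lag_cv = 0.25, nonaggregating_frac = p$frac,
                     noise_sd = 8)
  sim <- gen_tht_plate(truth, n_wells = 16, duration_s = horizon,
                       cycle_s = 350, seed = seed + i)
  write_plate_kinetics(sim$plate, file.path(out, paste0("tht_", cn, ".csv")))
  sim$truth$condition <- cn
  truth_all <- rbind(truth_all, sim$truth)
}
write.csv(truth_all, file.path(out, "tht_truth.csv"), row.names = FALSE)
cat(sprintf("ThT plates: %d conditions x 16 wells, %d cycles each\n",
            length(conditions), 742))

# FRAP: fresh (0 h) and aged (4 h) condensates, with and without chaperone.
# Aging lowers the mobile fraction; the chaperone preserves it.
frap_design <- list(
  "alone_0h"     = list(mf = 0.35, th = 6),
  "alone_4h"     = list(mf = 0.12, th = 9),
  "chaperone_0h" = list(mf = 0.75, th = 4),
  "chaperone_4h" = list(mf = 0.70, th = 5))
for (i in seq_along(frap_design)) {
  d <- frap_design[[i]]
  ser <- gen_frap_series(frap_truth(mobile_fraction = d$mf, t_half_s = d$th,
                                    noise_sd = 0.01), seed = seed + 100 + i)
  write_frap_table(ser, file.path(out, paste0(
    "frap_", names(frap_design)[i], ".csv")))
}
truth_frap <- data.frame(series = names(frap_design),
                         mobile_fraction = sapply(frap_design, `[[`, "mf"),
                         t_half_s = sapply(frap_design, `[[`, "th"))
write.csv(truth_frap, file.path(out, "frap_truth.csv"), row.names = FALSE)
cat("FRAP series: 4 (fresh/aged x with/without chaperone)\n")

# TCCD: two-channel acquisitions at a known hetero-oligomer fraction
pp <- gen_photon_pair(tccd_truth(n_bursts_per_channel = 300,
                                 coincident_fraction = 0.4,
                                 duration_s = 50), seed = seed + 200)
write_photon_trace(pp$a, file.path(out, "tccd_substrate.csv"))
write_photon_trace(pp$b, file.path(out, "tccd_chaperone.csv"))
write.csv(data.frame(coincident_time_ms = pp$truth$coincident_a_ms),
          file.path(out, "tccd_truth.csv"), row.names = FALSE)
cat(sprintf("TCCD pair: %d bursts/channel, true coincident fraction 0.40\n",
            300))

# Turbidity: salt titration; condensation rises with NaCl
salt <- seq(0, 500, by = 100)
for (i in seq_along(salt)) {
  ts <- gen_turbidity_series(od_max = 0.55 * salt[i] / 500 + 0.02,
                             rate_per_s = 0.02 + 0.0001 * salt[i],
                             noise_sd = 0.004, duration_s = 300, dt_s = 10,
                             seed = seed + 300 + i,
                             well_id = sprintf("NaCl_%dmM", salt[i]))
  df <- data.frame(time_s = ts$time_s, ts$od, check.names = FALSE)
  write.csv(df, file.path(out, sprintf("turbidity_nacl_%03d.csv", salt[i])),
            row.names = FALSE)
}
cat(sprintf("Turbidity: %d NaCl conditions x 30 readings\n", length(salt)))
cat("done; raw synthetic datasets under", out, "\n")
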
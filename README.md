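# aggkinetics

Analysis pipeline for in vitro protein aggregation and liquid–liquid phase
separation experiments, written for studies of aggregation-prone
low-complexity domains (the TDP-43 LCD being the motivating case) and the
small heat shock protein chaperones that modulate them. The package covers
five measurement modalities with one tested code path each, plus
seed-deterministic synthetic-data generators with recorded ground truth so
the whole pipeline is testable without instrument data.

## What it computes

**ThT fibrillation kinetics.** Each well's fluorescence trace is fitted to
the Boltzmann sigmoid

    F(t) = Fi + (Ff − Fi) / (1 + exp((t50 − t)/k))

from which the pipeline derives the elongation rate `(Ff − Fi)/(4k)` (the
maximal slope, at `t50`), the lag time — both the baseline-dependent form
`4·k·Fi/(Ff − Fi) + t50 − 2k` and the tangent form `t50 − 2k`, which
coincide exactly when `Fi = 0` — the endpoint intensity, and the chaperone
efficacy statistic

    %Protection = (ΔI − ΔI_chaperone)/ΔI × 100 .

**Survival analysis of aggregation onset.** Wells are coded as aggregation
events (1, stamped with their lag time) or right-censored wells (0, at the
final assay time), then analyzed with the Kaplan–Meier product-limit
estimator, the log-rank (Mantel–Cox) test with hazard ratios
`(O_a/E_a)/(O_b/E_b)` and 95% CIs, Holm-adjusted pairwise comparisons, and
a mean time to failure from a sigmoid fit to the survival curve.

**FRAP.** Three-ROI recovery series undergo full-scale normalization
(background subtraction, reference double-normalization, rescale so the
pre-bleach mean is 1 and the first post-bleach frame is 0), then an
exponential recovery fit `a(1 − e^(−bt))` gives the mobile fraction `a` and
half-time `ln 2 / b`.

**TCCD.** Photon-count traces are thresholded at
`P_center + 2×FWHM` from a Gaussian fit to the count histogram; peaks are
local maxima above threshold at ≥ 40 ms separation; peaks in the two color
channels within 10 ms are matched one-to-one and reported as percent
coincidence of the reference channel.

**Condensation quantifications.** Sequence-composition extinction
coefficients (`5500·nTrp + 1490·nTyr`, plus cystine term), degree of
labeling, Beer–Lambert dilute-phase fractions, and turbidity ΔOD.

## Worked example

```r
library(aggkinetics)

# simulate one aggregating well and fit it
sim <- gen_tht_plate(tht_truth(noise_sd = 0, lag_cv = 0), n_wells = 1, seed = 7)
fit <- fit_boltzmann(sim$plate$traces[[1]])
fit
#> <boltzmann_fit> Fi = 100, Ff = 1100, t50 = 3600 s, k = 400 s (r2 = 1.0000)
kinetic_summary(fit, sim$plate$traces[[1]])
#> <kinetic_summary> elongation 0.625 a.u./s, lag 2960 s (tangent 2800 s), dI 1000
```

The elongation rate is `(1100 − 100)/(4·400) = 0.625` a.u./s; the lag of
2960 s exceeds the tangent value 2800 s by `4·k·Fi/(Ff − Fi) = 160` s, the
baseline-dependent term. A survival comparison of two conditions:

```r
a <- event_table(paste0("a", 1:3), c(1, 1, 1), c(10, 20, 30), "a")
b <- event_table(paste0("b", 1:3), c(1, 1, 1), c(40, 50, 60), "b")
logrank_test(a, b)
#> <logrank_result> chi2 = 5.052, p = 0.0246, HR(a/b) = 4.217 [0.5523, 32.2]
```

Group a aggregates strictly earlier, so its hazard ratio relative to b is
well above 1. And the sequence-derived working extinction coefficient of the
His6-TEV TDP-43 LCD expression construct:

```r
extinction_coefficient(construct_fasta("tdp43_lcd_construct"))
#> [1] 19480
```

## The analysis workflow

`analysis/` holds numbered drivers that run the full simulated study and
write tidy tables under `results/`:

| script | writes |
|---|---|
| `01_simulate_datasets.R` | raw synthetic plates/series + truth tables (`results/data/`) |
| `02_tht_kinetics.R` | per-well fits, elongation rates, `%protection` |
| `03_survival.R` | KM curves, pairwise log-rank + hazard ratios, MTTF |
| `04_frap.R` | mobile fraction / half-time vs truth |
| `05_tccd.R` | noise models, peak counts, % coincidence + chance level |
| `06_condensation.R` | ΔOD titration, dilute-phase fractions |

Run in order from the repository root, e.g.
`Rscript analysis/01_simulate_datasets.R`. In the shipped configuration the
chaperoned conditions come out with >70% protection, hazard ratios ≈ 0.16
versus the substrate alone, and preserved FRAP mobile fractions after
aging, while the inert-protein control changes nothing — the qualitative
fingerprint these assays are designed to detect.

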
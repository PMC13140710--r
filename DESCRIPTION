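Package: aggkinetics
Title: Aggregation Kinetics, Survival, FRAP and Two-Color Coincidence
    Analysis for Protein Condensation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for in vitro protein aggregation and
    liquid-liquid phase separation experiments: Boltzmann-sigmoid fitting
    of thioflavin-T fibrillation kinetics with lag-time, elongation-rate
    and percent-protection summaries; Kaplan-Meier and log-rank (Mantel-Cox)
    analysis of per-well aggregation events with hazard ratios and mean
    time to failure; full-scale normalization and exponential-recovery
    fitting of fluorescence recovery after photobleaching (FRAP) series;
    two-color coincidence detection (TCCD) burst analysis of photon-count
    traces; and scalar biochemical quantifications (extinction coefficients
    from sequence composition, degree of labeling, dilute-phase fraction,
    turbidity delta-OD). Includes seed-deterministic synthetic-data
    generators with known ground truth for every assay so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    minpack.lm,
    survival,
    seqinr,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
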
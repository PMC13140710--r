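---
title: "Quantifying protein aggregation and condensation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein aggregation and condensation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggkinetics)
```

`aggkinetics` implements the quantitative analysis layer of a class of
in vitro experiments on aggregation-prone, phase-separating proteins —
typified by the TDP-43 low-complexity domain (LCD) and its small heat shock
protein (sHsp) chaperones HspB1 and HspB5: agitated thioflavin-T (ThT)
fibrillation kinetics, per-well survival analysis of aggregation onset,
fluorescence recovery after photobleaching (FRAP) of condensates,
single-molecule two-color coincidence detection (TCCD), and turbidity /
dilute-phase condensation measurements. Because raw instrument data for such
studies are rarely deposited, the package pairs every analysis with a
seed-deterministic synthetic-data generator whose ground truth is recorded,
so each estimator can be validated end to end.

This vignette explains the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic data do and do not
establish about real data.

## ThT fibrillation kinetics

### Model

Amyloid formation monitored by ThT fluorescence follows a sigmoid: a lag
phase (primary nucleation), a growth phase (elongation), and a plateau. Each
well's trace $F(t)$ is fitted to the Boltzmann sigmoid

$$F(t) = F_i + \frac{F_f - F_i}{1 + e^{(t_{50} - t)/k}}$$

with baseline $F_i$, plateau $F_f$, midpoint $t_{50}$ (s) and slope
parameter $k$ (s). This is an empirical descriptor, not a mechanistic
nucleation–elongation model (deliberately out of scope): its four parameters
summarize the curve well enough to compare conditions.

Derived quantities (`kinetic_summary()`):

* **Elongation rate** $= (F_f - F_i)/(4k)$, the maximal slope, attained at
  $t_{50}$. A finite-difference check of this identity against the fitted
  curve is part of the test suite.
* **Lag time**, two forms. The tangent construction intersects the
  midpoint tangent with the baseline *level*; solving the tangent equation
  against $F = F_i$ yields
  $t_{lag} = \frac{4 k F_i}{F_f - F_i} + t_{50} - 2k$, which carries a
  baseline-dependent term, while the classical baseline-free construction
  gives $t_{lag} = t_{50} - 2k$. The two coincide exactly when $F_i = 0$
  and diverge otherwise. Both are reported
  (`t_lag_paper_s`, `t_lag_tangent_s`); the baseline-dependent form is the
  default event time because it is the form conventionally quoted with this
  equation set, and transparency about the discrepancy is preferable to
  silently picking one.
* **Endpoint** = mean of the final three *raw* points, robust to a
  last-cycle artifact, deliberately not the fitted $F_f$.
* **Amplitude** $\Delta I = F_f - F_i$ (fitted when the fit converges, raw
  maximum minus baseline mean otherwise), feeding percent protection:
  $$\%\text{Protection} = \frac{\Delta I - \Delta I_{chap}}{\Delta I}
  \times 100,$$
  which is negative when the chaperone *increases* the amplitude — a real
  phenomenon at substoichiometric ratios, so the value is intentionally
  unclipped.

### Fitting choices

Nonlinear least squares uses the Levenberg–Marquardt implementation in
`minpack.lm`. Starting values: $F_i$ and $F_f$ from the means of the first
and last 5% of points, $t_{50}$ from the first midpoint crossing, $k$ at one
twentieth of the time span. No box constraints are imposed; instead a fit is
reported `converged` only if the optimizer succeeded, $r^2 \ge$ `min_r2`
(default 0.5), $k > 0$, and $t_{50}$ lies within the observed range plus one
span. Exactly flat traces short-circuit with reason `"no transition"`
rather than being fitted.

### Event coding

A well is an aggregation **event** (`detect_event()`, coded 1) when its fit
converged, $\Delta I >$ `min_fold` × (SD of the first `n_baseline` points)
and $r^2 \ge$ `min_r2`. Defaults `min_fold = 10`, `n_baseline = 10`,
`min_r2 = 0.9`: "significant increase in ThT" is not defined quantitatively
in the assay tradition, so the defaults were chosen once such that a
noiseless synthetic plate is classified perfectly, and are exposed as
parameters. Otherwise the well is right-censored (coded 0) at the final
assay time — the natural censoring time, since the well was observed not to
aggregate for exactly that long. Event times are the chosen lag formula,
clipped to be positive (half the sampling interval at minimum).

A caveat the package surfaces rather than hides: the baseline window
(`n_baseline` cycles) must end before the transition begins. On a 350-s
cycle, a midpoint at 3600 s puts the rise inside a 10-cycle window; event
coding is therefore meaningful on the long-assay regime (~10-h lags over 742
cycles, the regime of chaperone titrations), which is what the analysis
scripts and survival simulations use. Fitting accuracy itself is
unaffected.

## Survival analysis of aggregation onset

Per-well events feed a standard right-censored survival analysis: the
product-limit (Kaplan–Meier) estimator, the Mantel–Cox log-rank test, and
hazard ratios from the observed/expected event counts,
$HR = (O_a/E_a)/(O_b/E_b)$, with 95% CIs from the normal approximation on
the log scale with $SE = \sqrt{1/E_a + 1/E_b}$. These are standard
computations and are delegated to the `survival` package behind the module
surface; the test suite checks them against hand-rolled enumeration oracles
(direct product-limit loops and per-event-time 2×2 tables) rather than
trusting either implementation alone. A group with zero events yields
$HR = +\infty$, flagged, not an error. Pairwise comparisons against the
substrate-alone condition are Holm-adjusted — the assay tradition reports
pairwise comparisons without naming an adjustment, and Holm controls the
familywise error without independence assumptions.

**Mean time to failure** fits a *decreasing* sigmoid
$S(t) = S_f + (1 - S_f)/(1 + e^{(t - t_{50})/k})$ to the KM step function
(upper plateau fixed at 1, lower plateau free, $k > 0$ by bound) and
reports the tangent onset $t_{50} - 2|k|$. The baseline-dependent lag form
is *not* used here: a survival curve starts at 1, so the $F_i$-dependent
term has no geometric meaning on this axis. Fewer than three distinct event
times, or an all-censored table, returns `NA` with a reason.

## FRAP of condensates

### Normalization

Raw three-ROI data (bleached region, whole-condensate reference,
off-condensate background) undergo full-scale normalization in three steps:

1. background subtraction of ROI and reference;
2. double normalization
   $dn(t) = \frac{roi(t)}{ref(t)} \cdot
   \frac{\overline{ref}_{pre}}{\overline{roi}_{pre}}$, which removes
   acquisition photobleaching (it affects ROI and reference alike) and
   scales the pre-bleach mean to 1;
3. full-scale rescale $fs(t) = \frac{dn(t) - dn(t_0)}{1 - dn(t_0)}$, with
   $t_0$ the *single* first post-bleach frame (the cited tooling's
   convention, not an average), pinning that frame to exactly 0.

After these steps the recovery plateau reads directly as the mobile
fraction. Degenerate inputs fail loudly: a reference at or below background,
or $dn(t_0) \ge 1$ ("no bleach detected").

### Recovery model

Post-bleach data are fitted to $fs(t) = a(1 - e^{-bt})$; mobile fraction
$= a$, half-time $= \ln 2 / b$ — reported from the fitted rate, not read
off the curve, for noise robustness (identical for noiseless data). A
double-exponential option (`model = "double"`) exists for biphasic
recoveries; the single-exponential is the default because condensate FRAP
in this assay class is summarized by a single half-time. Spatial
diffusion models (Soumpasis/Axelrod) are out of scope: whole- and
half-condensate bleaching geometries are processed identically, with the
geometry recorded as metadata by the caller. A flat recovery returns mobile
fraction ≈ 0 with a flag instead of failing, since "immobile" is a finding,
not an error.

## Two-color coincidence detection

Binned photon-count traces from two spectrally distinct channels are
processed per channel and then matched:

1. **Noise model** (`fit_noise()`): a Gaussian is least-squares-fitted to
   the histogram of per-bin counts. The histogram is mode-dominated, so
   bursts in the tail barely perturb the fit (a robustness test caps the
   threshold shift at 5% under 1% burst bins of 20σ). Binning uses
   Freedman–Diaconis widened to at least one count — counts are integers,
   and sub-integer bins would comb the histogram. From the fit:
   $FWHM = 2\sqrt{2\ln 2}\,\sigma$ and the detection threshold
   $= P_{center} + 2 \times FWHM$.
2. **Peak finding** (`find_peaks()`): local maxima above threshold, kept
   greedily in descending height order subject to a minimum separation
   (default 40 ms, so a slowly diffusing oligomer spread over several bins
   counts once). Plateau ties keep the first bin; peak time is the bin
   center.
3. **Coincidence** (`coincidence()`): candidate pairs within the window
   (default 10 ms) are matched greedily by smallest |Δt|, each peak used at
   most once. The pair set is symmetric under channel swap, and on
   instances where candidates do not compete for a peak the greedy match is
   maximum-cardinality (verified against an exhaustive matcher on small
   instances). Percent coincidence is normalized by the *reference*
   channel's peak count; a reference channel with no peaks yields an
   undefined (NA, flagged) percentage, never 0. Both reference directions
   are supported.

No chance-coincidence correction is applied — consistent with how the
statistic is conventionally reported — but a Monte-Carlo estimate of the
chance level (`chance_coincidence()`) is emitted as a diagnostic.

The trace bin width is the caller's choice; the default of 1 ms makes the
40-ms separation and 10-ms window exact integer multiples of the bin and
comfortably resolves millisecond-scale diffusion bursts in a 10-s
acquisition.

## Scalar quantifications

* **Extinction coefficient** from composition:
  $\varepsilon_{280} = 5500\,n_{Trp} + 1490\,n_{Tyr}$ (reduced). The
  oxidized variant adds 125 per cystine with every cysteine assumed
  disulfide-bonded and an unpaired cysteine counted as a half-cystine
  rounded up — the counting that reproduces the standard calculators'
  outputs for odd-cysteine proteins such as the HspB1 α-crystallin domain
  (single Cys137; 5500 + 2·1490 + 125 = 8605). Reduced-mode values are
  additive over concatenation, which the suite checks as a property.
  FASTA fixtures for the three constructs of interest ship with the
  package (`construct_fasta()`); note that the TDP-43 LCD *expression
  construct* carries an uncleaved His6-TEV leader whose TEV-site tyrosine
  raises the working coefficient to 19,480 M⁻¹cm⁻¹ from the bare region's
  17,990 (3 Trp + 1 Tyr) — the bundled leader sequence is labelled as a
  reconstruction, since only its single tyrosine (and absence of other
  chromophores) matters to the coefficient.
* **Degree of labeling**: the printed algebra for this quantity in the
  assay tradition mixes a molar concentration with a molecular-weight
  division and cannot be reconciled dimensionally; the package implements
  the standard dye:protein molar ratio,
  $DOL = 100 \cdot \frac{A_{dye}/\varepsilon_{dye}}
  {(A_{280} - CF \cdot A_{dye})/\varepsilon_{protein}}$, which uses every
  published constant (Cy5 correction factor 0.08, both ε values), is
  invariant to a common gain on both absorbances, and reproduces the
  intended behavior (percentages above 100 for over-labeled proteins).
  Molecular weight is accepted as metadata but unused.
* **Dilute-phase fraction**: Beer–Lambert on the supernatant absorbance;
  the path length is configurable (default 0.1 cm, a common microvolume
  cuvette path — instrument-dependent and not standardized). Fractions
  slightly above 1 are tolerated (measurement error); above 1.05 they are
  flagged.
* **Turbidity ΔOD**: endpoint change in OD per wavelength. The default
  uses three-point endpoint means to damp last-cycle noise;
  `literal_endpoint = TRUE` restores the single-final-point rule. The
  statistic is antisymmetric under time reversal, checked as a property.

## The synthetic-data generators

Each generator emulates the statistical structure its analysis assumes and
records the generating truth:

* **ThT plates**: per-well midpoints are drawn *lognormally* with mean
  `t50_s` and CV `lag_cv` — nucleation times are strictly positive and
  right-skewed; the well-to-well scatter seen in real plates motivates the
  CV parameter, and the lognormal is a choice (the assay tradition reports
  scatter but no distribution). A Bernoulli `nonaggregating_frac` produces
  flat, censorable wells. Defaults ($F_i = 100$, $F_f = 1100$,
  $t_{50} = 3600$ s, $k = 400$ s, 2% amplitude noise, CV 0.2) describe a
  clean tenfold transition; survival-oriented simulations use the long
  assay (~10-h midpoints, 742 × 350-s cycles, the chaperone-titration
  regime) for the baseline-window reason above.
* **FRAP**: pre-bleach plateau, instantaneous drop by `bleach_depth`,
  recovery `mobile_fraction * (1 - 2^(-t/t_half))`, mild linear
  acquisition-photobleaching decay applied to ROI and reference alike, and
  constant background — constructed so that noiseless normalization
  returns the closed form *exactly* (to 1e-12), making the generator the
  oracle for the fitter. Default sampling, ~90 s at 0.171-s intervals
  (526 post-bleach frames), matches typical confocal FRAP of micron-scale
  condensates.
* **TCCD**: background per bin is truncated-rounded Gaussian; bursts are
  Gaussian-profile excursions (FWHM `burst_width_ms`; burst shape is
  unspecified in the assay tradition, Gaussian is the choice) at uniform
  times with a minimum slot gap of max(3 × width, 45 ms) laid down
  *jointly across channels*. The joint layout means channel-exclusive
  bursts never fall inside another channel's 10-ms window and same-channel
  bursts stay resolvable at the 40-ms separation — the dilute regime the
  assay operates in, and the construction that makes the truth fraction
  recoverable by ideal detection. Coincident partners share a center time
  within ±2 ms jitter (inside the window). Chance coincidence in *real*
  data is therefore not emulated by default — that is what the Monte-Carlo
  diagnostic is for. An occupancy guard rejects configurations above 20%
  expected burst occupancy.
* **Turbidity**: saturating exponential per wavelength with configurable
  wavelength scale factors (defaults 1 / 0.7 / 0.4 for 340 / 400 / 600 nm
  — scattering falls with wavelength; free parameters, not calibrated
  claims), 10-s sampling over 30 cycles by default.

No instrument noise magnitudes are published for this assay class; all
noise defaults are free parameters chosen once at values a practitioner
would call realistic (2% amplitude for plate readers, 1–2% relative for
confocal intensities, shot-noise-like counts for photon traces).

**What passing tests do and do not show.** The generators share the
parametric forms the estimators fit (by design, to make truth recoverable),
so parameter-recovery results certify the estimation machinery — not
robustness to model misspecification, baseline drift, evaporation,
double-sigmoid kinetics, condensate drift during FRAP, spectral crosstalk,
or detector afterpulsing, none of which are emulated. The
normalization/threshold/matching logic, by contrast, is model-free and
transfers directly.

## Problem sizes and numerical tolerances

The test suite and acceptance script run, among others: 200-well fitting
studies at 2% noise (median |t50 error| < 2%, elongation-rate bias < 1%);
1000-draw checks of the exact Fi = 0 lag identity (1e-9); product-limit and
log-rank enumeration oracles over random datasets of n ≤ 8 (1e-8); a
2000-pair null simulation of the log-rank test (empirical size within
[0.03, 0.07] at α = 0.05); 100-replicate FRAP recovery at 1% noise (≤ 5%
median error); and a 1000-burst TCCD recovery of a 50% coincident fraction
(within 3 binomial SE). These sizes were chosen to make sampling error
negligible relative to each tolerance while keeping the default suite in
the tens of seconds.

Degenerate inputs are first-class: flat traces, all-censored tables,
zero-variance photon traces, absent bleach drops, empty peak sets and
zero-event reference channels each have a defined, tested behavior (a
flagged result or a typed error), because real plates contain such wells.

## Limitations

* The Boltzmann sigmoid is descriptive; rate constants of nucleation and
  elongation mechanisms are not identifiable from it.
* Cross-plate normalization at different detector gains is out of scope —
  gain belongs in `meta` and comparisons should stay within plates.
* The KM→sigmoid mean-time-to-failure is a smoothing convention; with few
  events it is fragile, hence the three-event minimum and explicit flags.
* The oxidized-cystine counting reproduces the standard calculators but
  disulfide topology is not inferred from sequence; for proteins where the
  true pairing matters, supply the reduced value and correct externally.
* TCCD percent coincidence is normalized by detected reference-channel
  peaks; under very uneven labeling efficiencies the two reference
  directions differ, and neither is corrected for labeling — both are
  reported, interpretation is the caller's.
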
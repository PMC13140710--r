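# quant module: scalar biochemical quantifications — extinction coefficients
# from sequence composition, degree of labeling, dilute-phase fraction, and
# turbidity delta-OD.

#' Molar extinction coefficient at 280 nm from sequence composition
#'
#' Composition rule as used by standard protein-parameter calculators:
#' `eps = 5500 * nTrp + 1490 * nTyr` for the reduced protein; the oxidized
#' estimate assumes every cysteine participates in a disulfide and adds
#' `125 * ceiling(nCys / 2)` (an unpaired cysteine is counted as one
#' half-cystine, rounded up, matching the calculators' reported values for
#' odd-cysteine proteins).
#'
#' @param sequence Amino-acid string (one-letter codes, 20 standard
#'   residues; whitespace ignored), or a path to a FASTA file whose first
#'   record is used.
#' @param cystines `"reduced"` (default) or `"oxidized"`.
#' @return Integer molar extinction coefficient, 1/(M cm).
#' @export
#' @examples
#' extinction_coefficient("Y")                 # 1490
#' extinction_coefficient("WWYC", "oxidized")  # 12615
extinction_coefficient <- function(sequence,
                                   cystines = c("reduced", "oxidized")) {
  cystines <- match.arg(cystines)
  if (length(sequence) == 1L && file.exists(sequence) &&
      grepl("\\.(fa|fasta|faa)$", sequence, ignore.case = TRUE)) {
    rec <- seqinr::read.fasta(sequence, seqtype = "AA", as.string = TRUE)
    sequence <- as.character(rec[[1]])
  }
  s <- toupper(gsub("[[:space:]]", "", paste(sequence, collapse = "")))
  if (nchar(s) == 0L) stop_validation("empty sequence")
  letters_ok <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% letters_ok)
  if (length(bad))
    stop_validation("invalid residue '%s' at position %d", chars[bad[1]],
                    bad[1])
  n_trp <- sum(chars == "W")
  n_tyr <- sum(chars == "Y")
  n_cys <- sum(chars == "C")
  eps <- 5500 * n_trp + 1490 * n_tyr
  if (cystines == "oxidized") eps <- eps + 125 * ceiling(n_cys / 2)
  as.integer(eps)
}

#' Degree of labeling of a dye-protein conjugate
#'
#' Molar dye-to-protein ratio as a percentage, from the dye-peak absorbance
#' and the 280-nm absorbance corrected for the dye's own 280-nm
#' contribution:
#' `DOL = 100 * (A_dye / eps_dye) / ((A280 - CF * A_dye) / eps_protein)`.
#' Values above 100% indicate more than one dye per protein on average.
#'
#' @param a280 Absorbance at 280 nm.
#' @param a_dye Absorbance at the dye's peak.
#' @param eps_protein Protein molar extinction coefficient at 280 nm,
#'   1/(M cm).
#' @param eps_dye Dye molar extinction coefficient at its peak, 1/(M cm).
#' @param cf Dye correction factor at 280 nm (Cy5: 0.08).
#' @param mw_protein Optional protein molecular weight, g/mol; recorded for
#'   reporting only, not used by the molar-ratio formula.
#' @return Percentage (may exceed 100).
#' @export
degree_of_labeling <- function(a280, a_dye, eps_protein, eps_dye, cf = 0.08,
                               mw_protein = NULL) {
  assert_scalar_number(a280, "a280", lower = 0)
  assert_scalar_number(a_dye, "a_dye", lower = 0)
  assert_scalar_number(eps_protein, "eps_protein")
  assert_scalar_number(eps_dye, "eps_dye")
  if (eps_protein <= 0 || eps_dye <= 0)
    stop_validation("extinction coefficients must be positive")
  corrected <- a280 - cf * a_dye
  if (corrected <= 0)
    stop_validation("corrected protein absorbance (A280 - CF * A_dye = %.4g) must be positive",
                    corrected)
  100 * (a_dye / eps_dye) / (corrected / eps_protein)
}

#' Dilute-phase quantification of a condensation reaction
#'
#' Converts the supernatant absorbance to a concentration via Beer-Lambert
#' (`A = eps * c * l`) and reports the fraction of the input protein
#' remaining in the dilute phase. Fractions slightly above 1 can arise from
#' pipetting/measurement error; above `1 + tol` the result is flagged.
#'
#' @param a280_supernatant Supernatant absorbance at 280 nm (non-negative).
#' @param eps Molar extinction coefficient, 1/(M cm).
#' @param total_uM Input protein concentration, micromolar, positive.
#' @param path_cm Optical path length in cm (microvolume
#'   spectrophotometers normalize to 1 cm or use 0.1 cm; configurable).
#' @param tol Tolerance above 1 before the fraction is flagged.
#' @return An object of class `condensation_quant`: `total_conc_uM`,
#'   `dilute_conc_uM`, `dilute_fraction`, `flagged`.
#' @export
dilute_phase_fraction <- function(a280_supernatant, eps, total_uM,
                                  path_cm = 0.1, tol = 0.05) {
  assert_scalar_number(a280_supernatant, "a280_supernatant", lower = 0)
  assert_scalar_number(eps, "eps")
  assert_scalar_number(total_uM, "total_uM")
  assert_scalar_number(path_cm, "path_cm")
  if (eps <= 0 || total_uM <= 0 || path_cm <= 0)
    stop_validation("eps, total_uM and path_cm must be positive")
  dilute_uM <- a280_supernatant / (eps * path_cm) * 1e6
  frac <- dilute_uM / total_uM
  structure(list(total_conc_uM = total_uM, dilute_conc_uM = dilute_uM,
                 dilute_fraction = frac, flagged = frac > 1 + tol),
            class = "condensation_quant")
}

#' @export
print.condensation_quant <- function(x, ...) {
  cat(sprintf("<condensation_quant> %.3g / %.3g uM dilute (fraction %.3f)%s\n",
              x$dilute_conc_uM, x$total_conc_uM, x$dilute_fraction,
              if (x$flagged) " [exceeds input]" else ""))
  invisible(x)
}

#' Total change in optical density of a turbidity series
#'
#' Endpoint change in OD over the kinetic light-scattering assay. The
#' default averages the final three and first three readings to damp
#' last-cycle noise; `literal_endpoint = TRUE` uses the single final and
#' first readings.
#'
#' @param series A [turbidity_series()].
#' @param wavelength Wavelength label, e.g. `"600"`.
#' @param literal_endpoint Use single endpoint readings instead of
#'   three-point means.
#' @return Change in OD (may be negative for a falling series).
#' @export
delta_od <- function(series, wavelength, literal_endpoint = FALSE) {
  stopifnot(inherits(series, "turbidity_series"))
  wavelength <- as.character(wavelength)
  if (!wavelength %in% names(series$od))
    stop_validation("wavelength '%s' not in series (has: %s)", wavelength,
                    paste(names(series$od), collapse = ", "))
  od <- series$od[[wavelength]]
  if (length(od) < 2L)
    stop_validation("need at least 2 points to compute a change in OD")
  k <- if (literal_endpoint) 1L else min(3L, length(od) %/% 2)
  mean(tail(od, k)) - mean(head(od, k))
}

#' Path to a bundled construct sequence
#'
#' FASTA files shipped with the package for the three purified constructs
#' analyzed by the pipeline: the TDP-43 low-complexity domain (UniProt
#' Q13148 residues 267-414, bare region and His6-TEV expression construct)
#' and the alpha-crystallin domains of HspB1 (P04792 residues 86-169) and
#' HspB5 (P02511 residues 68-162). The expression construct's leader is a
#' reconstruction of the vector-encoded His6-TEV region (see the FASTA
#' header); its single TEV-site tyrosine is what distinguishes the
#' construct's extinction coefficient from the bare region's.
#'
#' @param which One of `"tdp43_lcd"` (bare region),
#'   `"tdp43_lcd_construct"`, `"hspb1_acd"`, `"hspb5_acd"`.
#' @return File path.
#' @export
construct_fasta <- function(which = c("tdp43_lcd", "tdp43_lcd_construct",
                                      "hspb1_acd", "hspb5_acd")) {
  which <- match.arg(which)
  fn <- c(tdp43_lcd = "tdp43_lcd_q13148_267-414.fasta",
          tdp43_lcd_construct = "tdp43_lcd_his6tev_construct_synthetic.fasta",
          hspb1_acd = "hspb1_acd_p04792_86-169.fasta",
          hspb5_acd = "hspb5_acd_p02511_68-162.fasta")[[which]]
  system.file("extdata", fn, package = "aggkinetics", mustWork = TRUE)
}
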
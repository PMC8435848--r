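# Elemental stoichiometry and lipid biomarker indices.

ATOMIC_WEIGHT <- c(C = 12.011, N = 14.007, P = 30.974)

# canonical names of the 22 fatty acids carried through the pipeline;
# the first seven are the components that typically dominate total FAs
FA_NAMES <- c(
  "14:0", "16:0", "16:1n-7", "18:1n-9c", "18:2n-6c", "20:5n-3", "22:6n-3",
  "12:0", "15:0", "16:2n-4", "16:3n-4", "17:0", "18:0", "18:1n-7",
  "18:3n-6", "18:3n-3", "18:4n-3", "20:0", "20:1n-9", "20:4n-6",
  "22:5n-3", "24:0"
)

# CSV-safe column name for a fatty acid ("16:1n-7" -> "fa_16_1n_7")
fa_col <- function(nm) paste0("fa_", gsub("[:-]", "_", nm))

canonical_fa <- function(x) {
  x <- gsub("\\s+", "", x)
  sub("^(\\d+:\\d+)(N)", "\\1n", x)
}

#' Convert an elemental mass to moles
#'
#' @param mass mass in micrograms; non-negative.
#' @param element `"C"`, `"N"` or `"P"`.
#' @return Amount in micromoles.
#' @export
to_molar <- function(mass, element) {
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass < 0)) {
    stop_invalid("`mass` must be finite and >= 0")
  }
  element <- as.character(element)
  if (!all(element %in% names(ATOMIC_WEIGHT))) {
    stop_invalid("`element` must be one of C, N, P")
  }
  mass / ATOMIC_WEIGHT[element]
}

#' Molar elemental ratios of a particulate-organic-matter sample
#'
#' @param poc,pon,pop particulate organic C, N and P, umol per litre of
#'   culture.
#' @return List with `poc_pon` and `pon_pop` (molar ratios). A zero
#'   denominator yields `NA` with a classed `bicompete_undefined_ratio`
#'   warning; the sample is retained.
#' @export
elemental_ratios <- function(poc, pon, pop) {
  if (any(!is.finite(c(poc, pon, pop))) || any(c(poc, pon, pop) < 0)) {
    stop_invalid("elemental pools must be finite and >= 0")
  }
  list(
    poc_pon = if (pon > 0) poc / pon else undefined_ratio("POC/PON"),
    pon_pop = if (pop > 0) pon / pop else undefined_ratio("PON/POP")
  )
}

#' Fatty-acid biomarker ratios
#'
#' The palmitoleic/palmitic ratio uses the 16:1n-7 isomer specifically;
#' EPA/DHA is 20:5n-3 over 22:6n-3. Both are elevated in diatoms relative
#' to dinoflagellates.
#'
#' @param fa named numeric vector of fatty-acid concentrations, ug/L; names
#'   are canonicalized (`"16:1 N-7"` matches `"16:1n-7"`).
#' @return List with `r_16_1_16_0` and `epa_dha`; zero denominators yield
#'   `NA` with a `bicompete_undefined_ratio` warning.
#' @export
fa_indices <- function(fa) {
  if (is.null(names(fa))) stop_invalid("`fa` must be a named vector")
  names(fa) <- canonical_fa(names(fa))
  get1 <- function(nm) if (nm %in% names(fa)) unname(fa[[nm]]) else 0
  p160 <- get1("16:0"); p161 <- get1("16:1n-7")
  epa <- get1("20:5n-3"); dha <- get1("22:6n-3")
  list(
    r_16_1_16_0 = if (p160 > 0) p161 / p160 else
      undefined_ratio("16:1/16:0"),
    epa_dha = if (dha > 0) epa / dha else undefined_ratio("EPA/DHA")
  )
}

#' Sterol biomarker index B/(B + D)
#'
#' Share of brassicasterol/epi-brassicasterol (a diatom marker) in the sum
#' of brassicasterol and dinosterol (a dinoflagellate marker); lies in
#' `[0, 1]` and increases with the diatom share of the community.
#'
#' @param brassicasterol_epi,dinosterol concentrations, ug/L; non-negative.
#' @return A value in `[0, 1]`, or `NA` (with warning) when both are zero.
#' @export
sterol_index <- function(brassicasterol_epi, dinosterol) {
  if (any(!is.finite(c(brassicasterol_epi, dinosterol))) ||
      brassicasterol_epi < 0 || dinosterol < 0) {
    stop_invalid("sterol concentrations must be finite and >= 0")
  }
  tot <- brassicasterol_epi + dinosterol
  if (tot <= 0) return(undefined_ratio("B/(B+D)"))
  brassicasterol_epi / tot
}

#' Major fatty-acid components of a profile
#'
#' @param fa named numeric vector of fatty-acid concentrations.
#' @param threshold_pct percentage-of-total threshold (default 5); a
#'   component is major when its share strictly exceeds the threshold.
#' @return Character vector of major component names.
#' @export
major_components <- function(fa, threshold_pct = 5) {
  if (is.null(names(fa)) || length(fa) == 0) {
    stop_invalid("`fa` must be a non-empty named vector")
  }
  total <- sum(fa)
  if (!is.finite(total) || total <= 0) {
    stop_invalid("total fatty-acid concentration must be > 0")
  }
  names(fa)[100 * fa / total > threshold_pct]
}

#' Normalize a lipid concentration to particulate organic carbon
#'
#' @param conc lipid concentration, ug/L.
#' @param poc particulate organic carbon, umol C/L; must be positive.
#' @return Carbon-normalized content, ug per mg C.
#' @export
carbon_normalize <- function(conc, poc) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop_invalid("`conc` must be finite and >= 0")
  }
  if (!is.finite(poc) || poc <= 0) return(undefined_ratio("per mg C") * conc)
  conc / (poc * ATOMIC_WEIGHT[["C"]] * 1e-3)
}

#' All composition indices of one sample
#'
#' Convenience wrapper computing the elemental ratios, fatty-acid and sterol
#' indices and carbon-normalized sterol contents of one composition sample.
#'
#' @param poc,pon,pop elemental pools, umol/L.
#' @param fa named fatty-acid vector, ug/L.
#' @param brassicasterol_epi,dinosterol sterols, ug/L.
#' @return One-row data.frame with `poc_pon`, `pon_pop`, `r_16_1_16_0`,
#'   `epa_dha`, `b_over_bd`, `brassicasterol_ug_mgC`, `dinosterol_ug_mgC`.
#' @export
composition_indices <- function(poc, pon, pop, fa, brassicasterol_epi,
                                dinosterol) {
  el <- elemental_ratios(poc, pon, pop)
  fi <- fa_indices(fa)
  data.frame(
    poc_pon = el$poc_pon, pon_pop = el$pon_pop,
    r_16_1_16_0 = fi$r_16_1_16_0, epa_dha = fi$epa_dha,
    b_over_bd = sterol_index(brassicasterol_epi, dinosterol),
    brassicasterol_ug_mgC = if (poc > 0)
      carbon_normalize(brassicasterol_epi, poc) else NA_real_,
    dinosterol_ug_mgC = if (poc > 0)
      carbon_normalize(dinosterol, poc) else NA_real_
  )
}
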
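# Monoisotopic masses of the elements handled by the subformula machinery
# (CHNOPS plus halogens), in Da.
MONOISOTOPIC <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069,
  F = 18.99840320, Cl = 34.96885271, Br = 78.9183376, I = 126.904468)

PROTON_MASS <- 1.00727646688

#' Parse an elemental formula string
#'
#' @param formula Formula such as `"C2H6O"` or `"C27H45NO6"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1)
    stop("formula must be a single string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  counts <- integer()
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    n <- gsub("[^0-9]", "", tok)
    n <- if (n == "") 1L else as.integer(n)
    if (!el %in% names(MONOISOTOPIC))
      stop("unknown element symbol '", el, "' in formula ", formula)
    counts[el] <- if (el %in% names(counts)) counts[[el]] + n else n
  }
  counts
}

#' Monoisotopic mass of a formula
#' @param formula Formula string or named count vector from
#'   [parse_formula()].
#' @return Mass in Da.
#' @export
formula_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(MONOISOTOPIC[names(counts)] * counts)
}

# All subformula masses of `counts` (including the empty and the full
# subformula), as a sorted numeric vector. Enumerates count vectors
# 0..n_e per element; feasible for small-molecule formulas.
subformula_masses <- function(counts) {
  masses <- 0
  for (el in names(counts)) {
    masses <- as.vector(outer(masses, (0:counts[[el]]) * MONOISOTOPIC[[el]],
                              `+`))
  }
  sort(masses)
}

#' Can a peak mass be explained as a subformula of the precursor formula?
#'
#' Tests whether some subformula of `precursor_formula` (any element counts
#' between zero and the precursor's), shifted by the adduct mass, has
#' monoisotopic mass within `tol_ppm` of `peak_mz`. Used to separate
#' plausible fragment peaks from noise peaks.
#'
#' @param peak_mz Peak m/z in Da (vectorized).
#' @param precursor_formula Neutral precursor formula, e.g. `"C2H6O"`.
#' @param tol_ppm Mass tolerance in ppm (default 10).
#' @param adduct_mass Mass added to the neutral fragment, default the proton
#'   mass for `[M+H]+` spectra. Set to 0 for neutral masses.
#' @return Logical vector, `TRUE` where decomposable.
#' @examples
#' subformula_decomposable(formula_mass("CH3") + 1.00727646688, "C2H6O")
#' @export
subformula_decomposable <- function(peak_mz, precursor_formula, tol_ppm = 10,
                                    adduct_mass = PROTON_MASS) {
  counts <- if (is.character(precursor_formula))
    parse_formula(precursor_formula) else precursor_formula
  if (any(counts < 0)) stop("element counts must be non-negative")
  masses <- subformula_masses(counts) + adduct_mass
  vapply(peak_mz, function(mz) {
    tol <- tol_ppm * 1e-6 * pmax(mz, masses)
    any(abs(masses - mz) <= tol)
  }, logical(1))
}
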
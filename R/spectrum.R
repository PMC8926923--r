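#' Construct a fragmentation spectrum
#'
#' A `Spectrum` is a peak list (m/z in Da, non-negative intensities) together
#' with precursor information. Peaks are stored sorted by ascending m/z.
#'
#' @param mz Numeric vector of peak m/z values (Da), all positive.
#' @param intensity Numeric vector of peak intensities, same length as `mz`,
#'   all non-negative.
#' @param id Opaque spectrum identifier.
#' @param precursor_mz Precursor m/z in Da (positive).
#' @param adduct Adduct label, e.g. `"[M+H]+"`.
#' @param collision_energy Collision energy in eV (numeric) or the string
#'   `"merged"` for pseudo-ramp spectra combined across energies.
#' @param ion_mode `"positive"` or `"negative"`.
#'
#' @return An object of class `Spectrum`: a list with elements `id`, `peaks`
#'   (a data.frame with columns `mz`, `intensity`), `precursor_mz`, `adduct`,
#'   `collision_energy` and `ion_mode`.
#' @examples
#' s <- spectrum(c(81.07, 109.1), c(100, 40), precursor_mz = 137.13)
#' n_peaks(s)
#' @export
spectrum <- function(mz, intensity, id = "spec", precursor_mz = NA_real_,
                     adduct = "[M+H]+", collision_energy = NA,
                     ion_mode = "positive") {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (anyNA(mz) || anyNA(intensity))
    stop("peak lists must not contain NA")
  if (any(mz <= 0)) stop("all m/z values must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!is.na(precursor_mz) && precursor_mz <= 0)
    stop("precursor_mz must be positive")
  ord <- order(mz)
  structure(
    list(id = id,
         peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
         precursor_mz = as.numeric(precursor_mz),
         adduct = adduct,
         collision_energy = collision_energy,
         ion_mode = match.arg(ion_mode, c("positive", "negative"))),
    class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("Spectrum '%s': %d peaks, precursor m/z %s, %s, CE %s\n",
              x$id, nrow(x$peaks),
              ifelse(is.na(x$precursor_mz), "?",
                     format(x$precursor_mz, digits = 8)),
              x$ion_mode, as.character(x$collision_energy)))
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param s A [spectrum()].
#' @return Integer peak count.
#' @export
n_peaks <- function(s) nrow(s$peaks)

is_spectrum <- function(x) inherits(x, "Spectrum")

stopifnot_spectrum <- function(x) {
  if (!is_spectrum(x)) stop("expected a Spectrum object")
  invisible(x)
}
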
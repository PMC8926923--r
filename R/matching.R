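ppm_window <- function(mz_a, mz_b, tol_ppm)
  abs(mz_a - mz_b) <= tol_ppm * 1e-6 * pmax(mz_a, mz_b)

#' Match peaks between two spectra within a ppm tolerance
#'
#' One-to-one greedy matching: candidate pairs within the tolerance are
#' sorted by ascending absolute mass difference and accepted closest-first,
#' each peak participating in at most one pair. This is deterministic and
#' mirrors common spectral-library practice.
#'
#' @param a,b [spectrum()] objects.
#' @param tol_ppm Mass tolerance in parts per million (default 7). A pair
#'   `(i, j)` is eligible when `|mz_a[i] - mz_b[j]| <=
#'   tol_ppm * 1e-6 * max(mz_a[i], mz_b[j])`.
#' @return Integer matrix with columns `index_a`, `index_b` (zero rows if
#'   nothing matches).
#' @export
match_peaks <- function(a, b, tol_ppm = 7) {
  stopifnot_spectrum(a); stopifnot_spectrum(b)
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  na <- n_peaks(a); nb <- n_peaks(b)
  empty <- matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("index_a", "index_b")))
  if (na == 0 || nb == 0) return(empty)
  ia <- rep(seq_len(na), times = nb)
  ib <- rep(seq_len(nb), each = na)
  mza <- a$peaks$mz[ia]; mzb <- b$peaks$mz[ib]
  ok <- ppm_window(mza, mzb, tol_ppm)
  if (!any(ok)) return(empty)
  ia <- ia[ok]; ib <- ib[ok]
  d <- abs(mza[ok] - mzb[ok])
  # closest pairs first; ties broken by index for determinism
  ord <- order(d, ia, ib)
  used_a <- logical(na); used_b <- logical(nb)
  out_a <- integer(); out_b <- integer()
  for (k in ord) {
    i <- ia[k]; j <- ib[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      out_a <- c(out_a, i); out_b <- c(out_b, j)
    }
  }
  ord2 <- order(out_a)
  cbind(index_a = out_a[ord2], index_b = out_b[ord2])
}

drop_precursor_peaks <- function(s, tol_ppm) {
  if (is.na(s$precursor_mz)) return(s)
  keep <- !ppm_window(s$peaks$mz, s$precursor_mz, tol_ppm)
  s$peaks <- s$peaks[keep, , drop = FALSE]
  rownames(s$peaks) <- NULL
  s
}

#' Cosine similarity (normalized dot product) of two spectra
#'
#' Each spectrum's intensity vector is (optionally square-root transformed
#' and) scaled to unit Euclidean norm after excluding peaks within
#' `tol_ppm` of the precursor m/z; the score is the sum of products of the
#' normalized intensities over the one-to-one peak matching from
#' [match_peaks()]. Precursor peaks are excluded because their high
#' intensity would overshadow the fragment peaks.
#'
#' @inheritParams match_peaks
#' @param sqrt_intensities Use square roots of intensities before
#'   normalization (a common variance-stabilizing variant).
#' @param exclude_precursor Drop peaks within `tol_ppm` of each spectrum's
#'   own precursor m/z before scoring (default TRUE).
#' @return Similarity in `[0, 1]`; 1 for a spectrum against itself.
#' @export
cosine_score <- function(a, b, tol_ppm = 7, sqrt_intensities = FALSE,
                         exclude_precursor = TRUE) {
  stopifnot_spectrum(a); stopifnot_spectrum(b)
  if (exclude_precursor) {
    a <- drop_precursor_peaks(a, tol_ppm)
    b <- drop_precursor_peaks(b, tol_ppm)
  }
  if (n_peaks(a) == 0 && n_peaks(b) == 0)
    stop("undefined similarity: both spectra empty after precursor exclusion")
  if (n_peaks(a) == 0 || n_peaks(b) == 0) return(0)
  va <- a$peaks$intensity; vb <- b$peaks$intensity
  if (sqrt_intensities) { va <- sqrt(va); vb <- sqrt(vb) }
  na2 <- sqrt(sum(va^2)); nb2 <- sqrt(sum(vb^2))
  if (na2 == 0 || nb2 == 0) return(0)
  m <- match_peaks(a, b, tol_ppm)
  if (nrow(m) == 0) return(0)
  val <- sum(va[m[, 1]] * vb[m[, 2]]) / (na2 * nb2)
  min(max(val, 0), 1)
}

#' Merge spectra acquired at several collision energies
#'
#' Builds a pseudo-ramp spectrum: each input's intensities are first
#' normalized to maximum 1 (so energies contribute on equal footing), all
#' peaks are pooled, peaks within `tol_ppm` are clustered, and each cluster
#' becomes one peak with intensity-weighted mean m/z and summed intensity.
#'
#' @param spectra Non-empty list of [spectrum()] objects sharing a
#'   precursor m/z (within `tol_ppm`).
#' @param tol_ppm Clustering tolerance in ppm (default 7).
#' @return A [spectrum()] with `collision_energy = "merged"`.
#' @export
merge_spectra <- function(spectra, tol_ppm = 7) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  if (length(spectra) == 0) stop("cannot merge an empty list of spectra")
  lapply(spectra, stopifnot_spectrum)
  pre <- vapply(spectra, function(s) s$precursor_mz, numeric(1))
  pre_ok <- pre[!is.na(pre)]
  if (length(pre_ok) > 1 &&
      any(!ppm_window(pre_ok[-1], pre_ok[1], tol_ppm * 2)))
    stop("precursor m/z values disagree beyond tolerance; refusing to merge")
  mz <- numeric(); int <- numeric()
  for (s in spectra) {
    if (nrow(s$peaks) == 0) next
    mx <- max(s$peaks$intensity)
    rel <- if (mx > 0) s$peaks$intensity / mx else s$peaks$intensity
    mz <- c(mz, s$peaks$mz); int <- c(int, rel)
  }
  if (length(mz) == 0) stop("cannot merge: all input spectra are empty")
  ord <- order(mz)
  mz <- mz[ord]; int <- int[ord]
  out_mz <- numeric(); out_int <- numeric()
  c_mz <- mz[1] * int[1]; c_int <- int[1]; c_ref <- mz[1]
  for (k in seq_along(mz)[-1]) {
    center <- if (c_int > 0) c_mz / c_int else c_ref
    if (ppm_window(mz[k], center, tol_ppm)) {
      c_mz <- c_mz + mz[k] * int[k]; c_int <- c_int + int[k]
      c_ref <- mz[k]
    } else {
      out_mz <- c(out_mz, if (c_int > 0) c_mz / c_int else c_ref)
      out_int <- c(out_int, c_int)
      c_mz <- mz[k] * int[k]; c_int <- int[k]; c_ref <- mz[k]
    }
  }
  out_mz <- c(out_mz, if (c_int > 0) c_mz / c_int else c_ref)
  out_int <- c(out_int, c_int)
  s1 <- spectra[[1]]
  spectrum(out_mz, out_int, id = paste0(s1$id, "_merged"),
           precursor_mz = if (length(pre_ok)) mean(pre_ok) else NA_real_,
           adduct = s1$adduct, collision_energy = "merged",
           ion_mode = s1$ion_mode)
}
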
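#' Spectral noise model
#'
#' Parameters of the distortion applied to reference spectra so that they
#' resemble biological-quality spectra. The distortion has four steps, in
#' order: a global relative mass bias drawn once per spectrum from
#' `N(0, sigma_mb^2)`; an independent relative mass deviation per peak from
#' `N(0, sigma_md^2)`; a multiplicative intensity distortion per peak from
#' `N(1, sigma_id_sq)` followed by baseline subtraction of
#' `subtract_frac * max` and discarding peaks below `floor_frac * max`; and
#' finally injection of `round(alpha * n)` realistic noise peaks drawn from
#' a [build_noise_peak_pool()] pool.
#'
#' The shipped presets are calibrated so that three standard deviations of
#' the global bias correspond to a 10 ppm shift (`medium`) or 15 ppm
#' (`high`), and of the per-peak deviation to 10 ppm / 20 ppm:
#' `medium = (sigma_mb (10/3)e-6, sigma_md (10/3)e-6, sigma_id_sq 1,
#' alpha 0.2)`, `high = ((15/3)e-6, (20/3)e-6, 2, 0.4)`, both with
#' `subtract_frac 0.03` and `floor_frac 1e-3`.
#'
#' @param preset `"medium"`, `"high"`, or `NULL` to set fields directly.
#' @param sigma_mb Relative (unitless) std of the global mass bias.
#' @param sigma_md Relative std of the per-peak mass deviation.
#' @param sigma_id_sq Variance of the multiplicative intensity distortion.
#' @param subtract_frac Fraction of the (post-distortion) maximum intensity
#'   subtracted from every peak; default 0.03.
#' @param floor_frac Relative intensity below which peaks are discarded;
#'   default 1/1000.
#' @param alpha Noise peaks injected per original peak; default per preset.
#' @return An object of class `noise_model` (a named list of the above).
#' @examples
#' m <- noise_model("medium")
#' 3 * m$sigma_mb * 1e6  # 10 ppm
#' @export
noise_model <- function(preset = c("medium", "high"), sigma_mb = NULL,
                        sigma_md = NULL, sigma_id_sq = NULL,
                        subtract_frac = 0.03, floor_frac = 1e-3,
                        alpha = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    def <- switch(preset,
      medium = list(sigma_mb = (10 / 3) * 1e-6, sigma_md = (10 / 3) * 1e-6,
                    sigma_id_sq = 1, alpha = 0.2),
      high   = list(sigma_mb = (15 / 3) * 1e-6, sigma_md = (20 / 3) * 1e-6,
                    sigma_id_sq = 2, alpha = 0.4))
  } else def <- list(sigma_mb = 0, sigma_md = 0, sigma_id_sq = 0, alpha = 0)
  m <- list(
    sigma_mb = if (is.null(sigma_mb)) def$sigma_mb else sigma_mb,
    sigma_md = if (is.null(sigma_md)) def$sigma_md else sigma_md,
    sigma_id_sq = if (is.null(sigma_id_sq)) def$sigma_id_sq else sigma_id_sq,
    subtract_frac = subtract_frac, floor_frac = floor_frac,
    alpha = if (is.null(alpha)) def$alpha else alpha)
  with(m, {
    if (sigma_mb < 0 || sigma_md < 0 || sigma_id_sq < 0 || alpha < 0)
      stop("noise parameters must be non-negative")
    if (subtract_frac < 0 || subtract_frac >= 1)
      stop("subtract_frac must be in [0, 1)")
  })
  structure(m, class = "noise_model")
}

#' Harvest a pool of realistic noise peaks from donor spectra
#'
#' Collects every donor peak whose m/z has no subformula decomposition of
#' the donor's precursor formula (within `tol_ppm`, adduct-shifted); such
#' peaks behave like genuine noise. Intensities are stored relative to the
#' donor spectrum's maximum intensity.
#'
#' @param spectra List of donor [spectrum()] objects.
#' @param formulas Character vector of neutral precursor formulas, one per
#'   donor spectrum (or a single formula recycled).
#' @param tol_ppm Decomposition tolerance in ppm (default 10).
#' @param adduct_mass See [subformula_decomposable()].
#' @return An object of class `noise_peak_pool`: a data.frame with columns
#'   `mz` and `rel_intensity`.
#' @export
build_noise_peak_pool <- function(spectra, formulas, tol_ppm = 10,
                                  adduct_mass = PROTON_MASS) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  formulas <- rep_len(formulas, length(spectra))
  mz <- numeric(); rel <- numeric()
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    if (nrow(s$peaks) == 0) next
    dec <- subformula_decomposable(s$peaks$mz, formulas[[k]], tol_ppm,
                                   adduct_mass)
    if (any(!dec)) {
      mx <- max(s$peaks$intensity)
      mz <- c(mz, s$peaks$mz[!dec])
      rel <- c(rel, if (mx > 0) s$peaks$intensity[!dec] / mx
               else s$peaks$intensity[!dec])
    }
  }
  structure(data.frame(mz = mz, rel_intensity = rel),
            class = c("noise_peak_pool", "data.frame"))
}

#' Distort a spectrum with a noise model
#'
#' Applies the four steps described in [noise_model()] using R's RNG, so
#' wrap calls in [set.seed()] for reproducibility.
#'
#' @param s A non-empty [spectrum()].
#' @param model A [noise_model()].
#' @param pool A [build_noise_peak_pool()] pool; may be `NULL`/empty only
#'   when no noise peaks are requested (`alpha * n < 0.5`).
#' @return The distorted [spectrum()].
#' @export
noisify <- function(s, model, pool = NULL) {
  stopifnot_spectrum(s)
  if (!inherits(model, "noise_model")) stop("model must be a noise_model")
  if (n_peaks(s) == 0) stop("cannot noisify an empty spectrum")
  mz <- s$peaks$mz
  int <- s$peaks$intensity
  # (1) global mass bias, one draw per spectrum
  delta_star <- stats::rnorm(1, 0, model$sigma_mb)
  mz <- mz + delta_star * mz
  # (2) per-peak mass deviation
  delta <- stats::rnorm(length(mz), 0, model$sigma_md)
  mz <- mz + delta * mz
  # (3) intensity distortion, baseline subtraction, floor
  eps <- stats::rnorm(length(int), 1, sqrt(model$sigma_id_sq))
  int <- int * eps
  mx <- max(int)
  if (mx > 0) {
    int <- int - model$subtract_frac * mx
    keep <- int >= model$floor_frac * mx
    mz <- mz[keep]; int <- int[keep]
  }
  # (4) inject noise peaks from the pool
  n_noise <- round(model$alpha * length(mz))
  if (n_noise >= 1) {
    if (is.null(pool) || nrow(pool) == 0)
      stop("noise peak pool is empty but ", n_noise,
           " noise peaks are required")
    idx <- sample.int(nrow(pool), n_noise, replace = n_noise > nrow(pool))
    recv_max <- if (length(int)) max(int) else 1
    mz <- c(mz, pool$mz[idx])
    int <- c(int, pool$rel_intensity[idx] * recv_max)
  }
  if (length(mz) == 0)
    return(spectrum(numeric(), numeric(), id = s$id,
                    precursor_mz = s$precursor_mz, adduct = s$adduct,
                    collision_energy = s$collision_energy,
                    ion_mode = s$ion_mode))
  spectrum(mz, pmax(int, 0), id = s$id, precursor_mz = s$precursor_mz,
           adduct = s$adduct, collision_energy = s$collision_energy,
           ion_mode = s$ion_mode)
}

#' Drop spectra with at most one peak
#'
#' Spectra reduced to zero or one peak by noisification carry no usable
#' fragmentation information and are removed.
#'
#' @param spectra List of [spectrum()] objects.
#' @return The sublist with at least two peaks each.
#' @export
filter_sparse <- function(spectra) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  Filter(function(s) n_peaks(s) >= 2, spectra)
}

#' Scale a noise model so the median original-vs-distorted cosine hits a
#' target
#'
#' Multiplies `sigma_id_sq` and `alpha` by a common factor, searched by
#' bisection, until the median cosine similarity between original and
#' distorted spectra reaches `target_median` (larger factor means more
#' distortion, hence lower cosine).
#'
#' @param spectra List of [spectrum()] objects to calibrate on.
#' @param model Starting [noise_model()].
#' @param pool Noise-peak pool (see [noisify()]).
#' @param target_median Desired median cosine in (0, 1).
#' @param tol_ppm Matching tolerance for the cosine (default 7).
#' @param seed RNG seed for the repeated distortions.
#' @param max_iter Bisection iterations (default 12).
#' @return A list with the scaled `model`, the scale `factor` applied, and
#'   the achieved `median_cosine`.
#' @export
tune_noise_model <- function(spectra, model, pool, target_median,
                             tol_ppm = 7, seed = 1, max_iter = 12) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  med_cos <- function(fac) {
    m <- model
    m$sigma_id_sq <- model$sigma_id_sq * fac
    m$alpha <- model$alpha * fac
    set.seed(seed)
    cs <- vapply(spectra, function(s) {
      sn <- noisify(s, m, pool)
      if (n_peaks(sn) == 0) 0
      else cosine_score(s, sn, tol_ppm = tol_ppm, exclude_precursor = FALSE)
    }, numeric(1))
    stats::median(cs)
  }
  lo <- 1e-3; hi <- 1
  while (med_cos(hi) > target_median && hi < 64) hi <- hi * 2
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    if (med_cos(mid) > target_median) lo <- mid else hi <- mid
  }
  fac <- sqrt(lo * hi)
  out <- model
  out$sigma_id_sq <- model$sigma_id_sq * fac
  out$alpha <- model$alpha * fac
  list(model = out, factor = fac, median_cosine = med_cos(fac))
}
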
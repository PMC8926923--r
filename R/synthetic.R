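#' Log-normal mixture specification for candidate scores
#'
#' Candidate score distributions of a single query are well described by a
#' mixture of log-normal components (often unimodal, sometimes with a
#' high-scoring secondary mode). This spec drives [gen_scores()].
#'
#' @param weights Component weights, summing to 1.
#' @param log_mean,log_sd Component parameters on the log scale
#'   (`log_sd > 0`).
#' @param n_samples Scores per query.
#' @param n_queries Number of queries (score arrays) to generate.
#' @return Object of class `score_mixture_spec`.
#' @export
score_mixture_spec <- function(weights = 1, log_mean = 0, log_sd = 1,
                               n_samples = 100, n_queries = 1) {
  k <- length(weights)
  if (length(log_mean) != k || length(log_sd) != k)
    stop("weights, log_mean and log_sd must have equal length")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(log_sd <= 0)) stop("log_sd must be positive")
  structure(list(weights = weights, log_mean = log_mean, log_sd = log_sd,
                 n_samples = n_samples, n_queries = n_queries),
            class = "score_mixture_spec")
}

#' Generate candidate score arrays from a log-normal mixture
#'
#' @param spec A [score_mixture_spec()].
#' @param seed Optional RNG seed for reproducibility.
#' @return List of `n_queries` numeric score vectors of length
#'   `n_samples`.
#' @export
gen_scores <- function(spec, seed = NULL) {
  if (!inherits(spec, "score_mixture_spec"))
    stop("spec must be a score_mixture_spec")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(spec$n_queries), function(q) {
    comp <- sample.int(length(spec$weights), spec$n_samples, replace = TRUE,
                       prob = spec$weights)
    stats::rlnorm(spec$n_samples, spec$log_mean[comp], spec$log_sd[comp])
  })
}

#' Generate a labeled hit/feature dataset
#'
#' Emulates confidence-model training data: each query yields a hit that
#' is correct with probability `fraction_correct`; correct hits have their
#' feature means shifted by the stated (signed) effect sizes relative to
#' standard-normal incorrect hits. Queries are single-candidate with
#' probability `p_single`; their comparison features
#' (`score_gap_runner_up`, `log_num_candidates`) are `NA`. For
#' multi-candidate queries the candidate count is log-normal and the
#' `log_num_candidates` feature is its actual log, shifted for correct
#' hits by the corresponding effect size.
#'
#' @param n_queries Number of queries (>= 10).
#' @param fraction_correct Probability a hit is correct, in (0, 1).
#' @param effect_sizes Named numeric vector of class-mean shifts; names
#'   must be schema feature names. Defaults favor score-type features,
#'   with a negative shift on `log_num_candidates` (correct hits tend to
#'   come from smaller candidate lists).
#' @param p_single Probability of a single-candidate query (default 0.1).
#' @param mean_log_candidates Mean of `log(n_candidates)` for incorrect
#'   multi-candidate queries (default `log(8)`).
#' @param seed Optional RNG seed.
#' @return data.frame with `query_id`, `correct`, `n_candidates` and one
#'   column per feature of [default_feature_schema()].
#' @export
gen_hit_dataset <- function(n_queries, fraction_correct = 0.5,
                            effect_sizes = c(
                              hit_score = 1.5, calibrated_score = 1.5,
                              score_gap_runner_up = 1.0,
                              log_num_candidates = -0.7,
                              explained_intensity = 0.8,
                              fingerprint_cardinality = 0.3,
                              tree_score = 0.2, fingerprint_quality = 0.2),
                            p_single = 0.1, mean_log_candidates = log(8),
                            seed = NULL) {
  if (n_queries < 10) stop("n_queries must be at least 10")
  if (fraction_correct <= 0 || fraction_correct >= 1)
    stop("fraction_correct must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  schema <- default_feature_schema()
  correct <- stats::runif(n_queries) < fraction_correct
  single <- stats::runif(n_queries) < p_single
  eff_of <- function(nm)
    if (nm %in% names(effect_sizes)) effect_sizes[[nm]] else 0
  lnc <- stats::rnorm(n_queries, mean_log_candidates, 0.8) +
    correct * eff_of("log_num_candidates")
  n_cand <- ifelse(single, 1L, pmax(2L, as.integer(round(exp(lnc)))))
  df <- data.frame(query_id = sprintf("q%05d", seq_len(n_queries)),
                   correct = correct, n_candidates = n_cand)
  for (nm in schema$name) {
    eff <- eff_of(nm)
    v <- if (nm == "log_num_candidates") {
      log(n_cand) + stats::rnorm(n_queries, 0, 0.3)
    } else {
      stats::rnorm(n_queries) + correct * eff
    }
    if (schema$requires_multiple_candidates[schema$name == nm])
      v[single] <- NA_real_
    df[[nm]] <- v
  }
  df
}

#' Generate a toy fragmentation spectrum with known decomposability
#'
#' Peaks are placed at adduct-shifted masses of random subformulas of the
#' precursor formula, so every regular peak is subformula-decomposable by
#' construction; optional planted noise peaks are drawn by rejection so
#' that they are provably not decomposable.
#'
#' @param precursor_formula Neutral formula, e.g. `"C10H14N2O5"`.
#' @param n_peaks Number of decomposable peaks (>= 2).
#' @param n_noise_peaks Planted non-decomposable peaks (default 0).
#' @param tol_ppm Tolerance used for the planted-noise rejection test.
#' @param adduct_mass Adduct shift; default the proton mass.
#' @param collision_energy Recorded collision energy (default 20).
#' @param id Spectrum identifier.
#' @param seed Optional RNG seed.
#' @return A [spectrum()] whose precursor m/z is the adduct-shifted
#'   precursor mass.
#' @export
gen_spectrum <- function(precursor_formula, n_peaks, n_noise_peaks = 0,
                         tol_ppm = 10, adduct_mass = PROTON_MASS,
                         collision_energy = 20, id = NULL, seed = NULL) {
  if (n_peaks < 2) stop("n_peaks must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  counts <- parse_formula(precursor_formula)
  masses <- unique(round(subformula_masses(counts), 9))
  masses <- masses[masses > 12]  # at least one heavy atom
  if (length(masses) < n_peaks)
    stop("formula ", precursor_formula, " has only ", length(masses),
         " distinct subformula masses; cannot place ", n_peaks, " peaks")
  mz <- sample(masses, n_peaks) + adduct_mass
  if (n_noise_peaks > 0) {
    lo <- 20; hi <- formula_mass(counts) + adduct_mass
    got <- numeric(0)
    while (length(got) < n_noise_peaks) {
      cand <- stats::runif(n_noise_peaks, lo, hi)
      ok <- !subformula_decomposable(cand, counts, tol_ppm, adduct_mass)
      got <- c(got, cand[ok])
    }
    mz <- c(mz, got[seq_len(n_noise_peaks)])
  }
  spectrum(mz, stats::runif(length(mz), 0.05, 1),
           id = if (is.null(id)) paste0("syn_", precursor_formula) else id,
           precursor_mz = formula_mass(counts) + adduct_mass,
           collision_energy = collision_energy)
}
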
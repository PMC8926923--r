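#' Bundle a hit score with its proxy-decoy scores
#'
#' The calibration machinery needs, for one query, the hit score together
#' with the scores of candidates from a very large structure database
#' ("proxy decoys", the hit itself excluded) and the candidate count `m` of
#' the target search database.
#'
#' @param hit_score Score of the top-ranked candidate (scorer units).
#' @param decoy_scores Numeric vector of proxy-decoy candidate scores,
#'   excluding the hit.
#' @param m Number of candidates in the target structure database
#'   (>= 1).
#' @param transform Monotone pre-transform making scores positive before
#'   the log: `"log"` requires positive scores; `"shift_log"` (default)
#'   first shifts by `1 - min(c(hit, decoys))` when any score is
#'   non-positive; `"identity"` uses the scores as-is (already log-scale).
#' @return An object of class `score_sample` with fields `y` (hit
#'   log-score), `ys` (decoy log-scores), `m`, and the transform record.
#' @export
score_sample <- function(hit_score, decoy_scores, m,
                         transform = c("shift_log", "log", "identity")) {
  transform <- match.arg(transform)
  if (m < 1) stop("m must be at least 1")
  x <- c(hit_score, decoy_scores)
  if (any(!is.finite(x))) stop("scores must be finite")
  shift <- 0
  if (transform == "shift_log" && min(x) <= 0) shift <- 1 - min(x)
  if (transform == "log" && min(x) <= 0)
    stop("log transform requires positive scores")
  tx <- switch(transform,
               identity = x,
               log = log(x),
               shift_log = log(x + shift))
  structure(list(y = tx[1], ys = tx[-1], m = as.numeric(m),
                 transform = transform, shift = shift),
            class = "score_sample")
}

#' Kernel bandwidth by Silverman's rule of thumb
#'
#' `h = 1.059223841 * sigma_hat * n^(-1/5)`, with `sigma_hat` the sample
#' standard deviation (denominator `n - 1`) of the decoy log-scores.
#'
#' @param ys Numeric vector of log-scores, length >= 2.
#' @param fallback Bandwidth returned (with a warning) when the sample
#'   standard deviation is zero; default `1e-6`.
#' @return List with `h` and `sigma_hat`.
#' @export
silverman_bandwidth <- function(ys, fallback = 1e-6) {
  n <- length(ys)
  if (n < 2) stop("need at least two scores for a bandwidth")
  sigma_hat <- stats::sd(ys)
  if (sigma_hat == 0) {
    warning("degenerate sample (zero spread); using fallback bandwidth")
    return(list(h = fallback, sigma_hat = 0))
  }
  list(h = 1.059223841 * sigma_hat * n^(-1 / 5), sigma_hat = sigma_hat)
}

#' E value of a hit score under the proxy-decoy kernel density
#'
#' Models the decoy log-scores by a Gaussian kernel density estimate with
#' Silverman bandwidth and returns the expected number of random
#' candidates, out of `m`, scoring at least as high as the hit:
#' `E = (m/n) * sum_i [1/2 - 1/2 erf((y - y_i) / (sqrt(2) h))]`.
#' Each bracket equals the upper tail of one Gaussian kernel, so `E/m` is
#' the survival function of the KDE at the hit log-score (the P value).
#'
#' @param sample A [score_sample()].
#' @param fallback Degenerate-spread fallback bandwidth, see
#'   [silverman_bandwidth()].
#' @return E value in `[0, m]`.
#' @seealso [p_value()], [calibrated_feature()]
#' @export
e_value <- function(sample, fallback = 1e-6) {
  if (!inherits(sample, "score_sample")) stop("expected a score_sample")
  bw <- silverman_bandwidth(sample$ys, fallback)
  # 1/2 - 1/2 erf((y - yi)/(sqrt(2) h)) == pnorm((yi - y)/h)
  (sample$m / length(sample$ys)) *
    sum(stats::pnorm((sample$ys - sample$y) / bw$h))
}

#' P value of a hit score
#'
#' `P = E / m`, the KDE tail probability of a score at least as high as the
#' hit's.
#'
#' @inheritParams e_value
#' @return P value in `[0, 1]`.
#' @export
p_value <- function(sample, fallback = 1e-6) {
  e_value(sample, fallback) / sample$m
}

#' Calibrated-score feature for the confidence model
#'
#' Returns `-log10(E + eps)`: a monotone transform of the E value so that
#' better (less chance-like) hits receive larger feature values.
#'
#' @inheritParams e_value
#' @param eps Numerical floor added before the log (default `1e-300`).
#' @return The feature value.
#' @export
calibrated_feature <- function(sample, eps = 1e-300, fallback = 1e-6) {
  -log10(e_value(sample, fallback) + eps)
}

#' Calibrate a candidate score table
#'
#' Batch interface over [e_value()]: for each query, the hit row
#' (`is_hit == TRUE`, or the top score when no flag is given) is calibrated
#' against the remaining candidate scores of the same query.
#'
#' @param candidates data.frame with columns `query_id`, `candidate_id`,
#'   `score`, optionally `is_hit` and `m` (target-database candidate count;
#'   defaults to the per-query candidate count).
#' @param transform See [score_sample()].
#' @return data.frame with one row per query: `query_id`, `candidate_id`
#'   (hit), `score`, `n_decoys`, `m`, `e_value`, `p_value`.
#' @export
calibrate_scores <- function(candidates,
                             transform = c("shift_log", "log", "identity")) {
  transform <- match.arg(transform)
  need <- c("query_id", "candidate_id", "score")
  if (!all(need %in% names(candidates)))
    stop("candidates must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(candidates, candidates$query_id), function(df) {
    hit_i <- if ("is_hit" %in% names(df) && any(df$is_hit))
      which(df$is_hit)[1] else which.max(df$score)
    decoys <- df$score[-hit_i]
    m <- if ("m" %in% names(df)) df$m[hit_i] else nrow(df)
    if (length(decoys) < 2) {
      ev <- NA_real_
    } else {
      ev <- e_value(score_sample(df$score[hit_i], decoys, m, transform))
    }
    data.frame(query_id = df$query_id[hit_i],
               candidate_id = df$candidate_id[hit_i],
               score = df$score[hit_i], n_decoys = length(decoys),
               m = m, e_value = ev, p_value = ev / m)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
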
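#' Ranked hit list
#'
#' Container for evaluation and estimation: hits ordered by descending
#' score (confidence), with correctness labels (evaluation mode) and/or
#' posterior error probabilities (estimation mode).
#'
#' @param score Numeric ranking score; the list is sorted by descending
#'   score (stable for ties).
#' @param correct Optional logical: is each hit a correct annotation?
#' @param posterior_error Optional numeric in `[0, 1]`: posterior error
#'   probability of each hit (one minus its confidence).
#' @param id Optional hit identifiers.
#' @return data.frame of class `ranked_hits`, ordered by descending score.
#' @export
ranked_hits <- function(score, correct = NULL, posterior_error = NULL,
                        id = NULL) {
  n <- length(score)
  if (n == 0) stop("empty hit list")
  if (!is.null(posterior_error) &&
      (anyNA(posterior_error) || any(posterior_error < 0 |
                                     posterior_error > 1)))
    stop("posterior_error values must lie in [0, 1]")
  df <- data.frame(id = if (is.null(id)) seq_len(n) else id,
                   score = as.numeric(score))
  if (!is.null(correct)) df$correct <- as.logical(correct)
  if (!is.null(posterior_error)) df$posterior_error <-
      as.numeric(posterior_error)
  df <- df[order(-df$score), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("ranked_hits", "data.frame"))
}

#' Exact FDR of the top-k hits
#'
#' The exact false discovery rate of a reported list is the number of
#' incorrect hits divided by the list size, computable only when
#' correctness labels are known. Returned as a percentage.
#'
#' @param hits A [ranked_hits()] with `correct` labels.
#' @param k Prefix length, `1 <= k <= nrow(hits)`; default the whole list.
#' @return Exact FDR in percent: `100 * FP_k / k`.
#' @examples
#' h <- ranked_hits(score = 10:1, correct = c(rep(TRUE, 8), FALSE, TRUE))
#' exact_fdr(h, 10)
#' @export
exact_fdr <- function(hits, k = nrow(hits)) {
  check_labels(hits)
  if (k < 1 || k > nrow(hits)) stop("k must be between 1 and the list size")
  100 * sum(!hits$correct[seq_len(k)]) / k
}

#' Estimated FDR and q values from posterior error probabilities
#'
#' Viewing the hits as Bernoulli trials, the expected number of incorrect
#' hits among the top k is the sum of their posterior error probabilities,
#' so the estimated FDR at rank k is the running mean
#' `(1/k) * sum_{j<=k} p_j`. Because the hits are ordered by confidence
#' (p non-decreasing), the estimate is monotone and equals the q-value
#' estimate.
#'
#' @param hits A [ranked_hits()] with `posterior_error`.
#' @return The hit table with columns `fdr_hat` and `q_hat` added.
#' @export
estimate_fdr_q <- function(hits) {
  if (is.null(hits$posterior_error))
    stop("hits must carry posterior_error values")
  p <- hits$posterior_error
  fdr_hat <- cumsum(p) / seq_along(p)
  hits$fdr_hat <- fdr_hat
  hits$q_hat <- fdr_hat
  hits
}

#' ROC curve and AUC of a labeled hit list
#'
#' Sweeps the score threshold over the ranked list and reports the true
#' positive rate `TP / (TP + FN)` against the false positive rate
#' `FP / (FP + TN)`; hits sharing a score enter together. The AUC is the
#' trapezoidal integral; a random ordering gives AUC 0.5 in expectation.
#'
#' @param hits A [ranked_hits()] with `correct` labels, both classes
#'   present.
#' @return List with `points` (data.frame `fpr`, `tpr` including (0,0) and
#'   (1,1)) and `auc`.
#' @export
roc_curve <- function(hits) {
  check_labels(hits)
  pos <- sum(hits$correct); neg <- sum(!hits$correct)
  if (pos == 0 || neg == 0)
    stop("AUC undefined: both correct and incorrect hits required")
  keep <- cumsum_threshold_points(hits$score)
  tp <- cumsum(hits$correct)[keep]
  fp <- cumsum(!hits$correct)[keep]
  pts <- data.frame(fpr = c(0, fp / neg), tpr = c(0, tp / pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Hop curve of a labeled hit list
#'
#' Like a ROC sweep, but both counts are normalized by the total number of
#' hits `N = TP + FN + TN + FP`: points are `(FP/N, TP/N)`. The curve
#' starts at the origin and ends at a point `(x, y)` with `x + y = 1`,
#' where `y` is the overall correct-hit ratio, so methods that differ in
#' how many hits they get right become comparable.
#'
#' @param hits A [ranked_hits()] with `correct` labels.
#' @return data.frame with columns `fp_frac`, `tp_frac` (first row (0,0)).
#' @export
hop_curve <- function(hits) {
  check_labels(hits)
  n <- nrow(hits)
  keep <- cumsum_threshold_points(hits$score)
  tp <- cumsum(hits$correct)[keep]
  fp <- cumsum(!hits$correct)[keep]
  data.frame(fp_frac = c(0, fp / n), tp_frac = c(0, tp / n))
}

#' Correct hits attainable at given exact-FDR levels
#'
#' For each level, reports the largest threshold-consistent prefix whose
#' exact FDR does not exceed the level, the number of correct hits in it,
#' and the score of its last hit (the usable score threshold). Hits that
#' share the cutoff score are included together.
#'
#' @param hits A [ranked_hits()] with `correct` labels.
#' @param fdr_levels Numeric FDR levels in percent (default
#'   `c(5, 10, 20, 30)`).
#' @return data.frame with columns `fdr_level`, `n_hits`, `n_correct`,
#'   `threshold` (NA where no prefix qualifies).
#' @export
fdr_threshold_report <- function(hits, fdr_levels = c(5, 10, 20, 30)) {
  check_labels(hits)
  ks <- which(cumsum_threshold_points(hits$score))
  fdr_k <- 100 * cumsum(!hits$correct) / seq_len(nrow(hits))
  out <- lapply(fdr_levels, function(lv) {
    ok <- ks[fdr_k[ks] <= lv]
    if (length(ok) == 0)
      return(data.frame(fdr_level = lv, n_hits = 0L, n_correct = 0L,
                        threshold = NA_real_))
    k <- max(ok)
    data.frame(fdr_level = lv, n_hits = k,
               n_correct = sum(hits$correct[seq_len(k)]),
               threshold = hits$score[k])
  })
  do.call(rbind, out)
}

#' Pair estimated q values with exact q values
#'
#' Requires both labels and posterior error probabilities. Exact q values
#' are the monotone lower envelope of the exact FDR sequence (the smallest
#' FDR at which each hit enters the output list); estimated q values come
#' from [estimate_fdr_q()]. The fraction of ranks where the estimate is
#' conservative (`q_hat >= q_exact`) is reported alongside.
#'
#' @param hits A [ranked_hits()] with both `correct` and
#'   `posterior_error`.
#' @return List with `pairs` (data.frame `rank`, `q_exact`, `q_hat`) and
#'   `frac_conservative`.
#' @export
qq_estimated_vs_exact <- function(hits) {
  check_labels(hits)
  if (is.null(hits$posterior_error))
    stop("hits must carry posterior_error values")
  n <- nrow(hits)
  fdr_exact <- cumsum(!hits$correct) / seq_len(n)
  q_exact <- rev(cummin(rev(fdr_exact)))
  q_hat <- estimate_fdr_q(hits)$q_hat
  pairs <- data.frame(rank = seq_len(n), q_exact = q_exact, q_hat = q_hat)
  list(pairs = pairs,
       frac_conservative = mean(q_hat >= q_exact))
}

check_labels <- function(hits) {
  if (!inherits(hits, "ranked_hits")) stop("expected a ranked_hits object")
  if (is.null(hits$correct) || anyNA(hits$correct))
    stop("hits must carry complete correctness labels")
  invisible(hits)
}

# TRUE at positions that are valid threshold cuts, i.e. the last hit of
# each tied-score block.
cumsum_threshold_points <- function(score) {
  n <- length(score)
  if (n == 1) return(TRUE)
  c(score[-n] != score[-1], TRUE)
}
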
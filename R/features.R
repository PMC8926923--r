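#' Feature schema for the confidence model
#'
#' Each feature carries an enforced direction: `+1` means larger values may
#' only increase confidence, `-1` only decrease it, `0` unconstrained. The
#' direction is enforced at training time (see [train_directional_svm()]),
#' so e.g. a high raw hit score can never lower the confidence of an
#' annotation. Features that compare the hit to other candidates (score gap
#' to the runner-up, candidate counts) are flagged
#' `requires_multiple_candidates` and are dropped in the single-candidate
#' regime.
#'
#' @param name Character vector of unique feature names.
#' @param direction Integer vector in `{-1, 0, 1}`.
#' @param requires_multiple_candidates Logical vector.
#' @param db_specific Logical vector; marks features tied to a particular
#'   search database.
#' @return data.frame of class `feature_schema`.
#' @export
feature_schema <- function(name, direction,
                           requires_multiple_candidates = FALSE,
                           db_specific = FALSE) {
  if (anyDuplicated(name)) stop("feature names must be unique")
  if (!all(direction %in% c(-1L, 0L, 1L)))
    stop("directions must be -1, 0 or +1")
  structure(data.frame(
    name = as.character(name), direction = as.integer(direction),
    requires_multiple_candidates =
      rep_len(requires_multiple_candidates, length(name)),
    db_specific = rep_len(db_specific, length(name)),
    stringsAsFactors = FALSE),
    class = c("feature_schema", "data.frame"))
}

#' Default feature schema
#'
#' The eight built-in hit features: the raw scorer output (`hit_score`),
#' the KDE-calibrated score `-log10(E)` (`calibrated_score`), the score gap
#' to the runner-up candidate, the log candidate count (more candidates
#' means a harder query, hence direction `-1`), the fraction of peak
#' intensity explained by the fragmentation tree, the cardinality and a
#' quality measure of the predicted molecular fingerprint, and the
#' fragmentation-tree score. Users can extend the schema with
#' [feature_schema()] and `rbind`.
#'
#' @return A [feature_schema()].
#' @export
default_feature_schema <- function() {
  feature_schema(
    name = c("hit_score", "calibrated_score", "score_gap_runner_up",
             "log_num_candidates", "explained_intensity",
             "fingerprint_cardinality", "tree_score", "fingerprint_quality"),
    direction = c(1L, 1L, 1L, -1L, 1L, 1L, 1L, 1L),
    requires_multiple_candidates =
      c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
}

#' Extract hit features from a scored candidate list
#'
#' The candidate list of one query is first restricted to candidates with
#' the same molecular formula as the highest-scoring candidate; the hit is
#' the top-scoring candidate of that restricted list (ties broken
#' lexicographically by candidate id). Comparison features are computed on
#' the restricted list; metadata features are passed through.
#'
#' @param candidates data.frame with columns `candidate_id`, `score` and
#'   optionally `formula` for one query.
#' @param metadata Named list of additional feature values for the hit
#'   (e.g. `calibrated_score`, `explained_intensity`, ...).
#' @param select `"hit"` (default) scores the top candidate; `"uniform"`
#'   picks a uniformly random candidate instead, which is how
#'   multi-candidate queries are converted into training rows for the
#'   single-candidate model (set the RNG seed outside for
#'   reproducibility).
#' @return List with `features` (named numeric vector; comparison features
#'   are `NA` for single-candidate queries), `n_candidates` (after formula
#'   restriction), `hit` (the selected candidate row).
#' @export
extract_features <- function(candidates, metadata = list(),
                             select = c("hit", "uniform")) {
  select <- match.arg(select)
  if (nrow(candidates) == 0) stop("empty candidate list for query")
  if (!all(c("candidate_id", "score") %in% names(candidates)))
    stop("candidates must have columns candidate_id and score")
  ord <- order(-candidates$score, as.character(candidates$candidate_id))
  candidates <- candidates[ord, , drop = FALSE]
  if ("formula" %in% names(candidates)) {
    candidates <- candidates[candidates$formula == candidates$formula[1], ,
                             drop = FALSE]
  }
  n <- nrow(candidates)
  hit_i <- if (select == "uniform") sample.int(n, 1) else 1L
  hit <- candidates[hit_i, , drop = FALSE]
  runner_up <- if (n >= 2) max(candidates$score[-hit_i]) else NA_real_
  feats <- c(
    hit_score = hit$score,
    score_gap_runner_up = if (n >= 2) hit$score - runner_up else NA_real_,
    log_num_candidates = if (n >= 2) log(n) else NA_real_)
  for (nm in names(metadata)) feats[[nm]] <- as.numeric(metadata[[nm]])
  list(features = feats, n_candidates = n, hit = hit)
}

#' Clip feature values to training caps and standardize
#'
#' Values are first clipped to the `[cap_min, cap_max]` range observed in
#' the training data (guarding against exaggerated decision values from
#' out-of-range features), then z-scored with the training mean and
#' standard deviation.
#'
#' @param features Named numeric vector, or a data.frame/matrix with one
#'   column per feature.
#' @param model A [train_directional_svm()] model.
#' @return Numeric matrix (rows = observations) in the model's feature
#'   order.
#' @export
standardize_and_cap <- function(features, model) {
  X <- as_feature_matrix(features, names(model$weights))
  for (j in seq_len(ncol(X))) {
    X[, j] <- pmin(pmax(X[, j], model$cap_min[j]), model$cap_max[j])
    X[, j] <- (X[, j] - model$center[j]) / model$scale[j]
  }
  X
}

as_feature_matrix <- function(features, feature_names) {
  if (is.null(dim(features))) {
    if (is.null(names(features)))
      stop("features must be named")
    features <- as.data.frame(as.list(features))
  }
  X <- as.matrix(as.data.frame(features))
  missing <- setdiff(feature_names, colnames(X))
  if (length(missing))
    stop("missing features: ", paste(missing, collapse = ", "))
  X <- X[, feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  X
}
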
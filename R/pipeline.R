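#' Score a query table and rank annotations by confidence
#'
#' The end of the workflow: every query row is scored with the
#' appropriate model from the registry (collision energy and
#' candidate-count regime, see [select_model()]), annotations are ordered
#' by confidence, and estimated q values are attached via
#' [estimate_fdr_q()] with posterior error `1 - confidence`. Queries with
#' an empty candidate list are assumed to have been excluded upstream.
#'
#' @param queries data.frame with columns `query_id`, `hit_id`,
#'   `structure_key`, `collision_energy`, `n_candidates`, plus one column
#'   per feature required by the registry's models. May have zero rows.
#' @param registry List of [train_directional_svm()] models covering the
#'   required energies and regimes.
#' @return data.frame sorted by descending confidence with columns
#'   `query_id`, `hit_id`, `structure_key`, `confidence`, `q_hat`.
#' @export
run_score_pipeline <- function(queries, registry) {
  need <- c("query_id", "hit_id", "structure_key", "collision_energy",
            "n_candidates")
  if (!all(need %in% names(queries)))
    stop("queries must have columns ", paste(need, collapse = ", "))
  if (nrow(queries) == 0)
    return(data.frame(query_id = character(), hit_id = character(),
                      structure_key = character(), confidence = numeric(),
                      q_hat = numeric()))
  conf <- vapply(seq_len(nrow(queries)), function(i) {
    ce <- queries$collision_energy[i]
    if (is.factor(ce)) ce <- as.character(ce)
    model <- select_model(registry, ce, queries$n_candidates[i])
    feats <- queries[i, names(model$weights), drop = FALSE]
    confidence_score(model, feats)
  }, numeric(1))
  out <- data.frame(query_id = queries$query_id, hit_id = queries$hit_id,
                    structure_key = queries$structure_key,
                    confidence = conf)
  out <- out[order(-out$confidence, out$query_id), , drop = FALSE]
  rh <- ranked_hits(out$confidence, posterior_error = 1 - out$confidence,
                    id = out$query_id)
  out$q_hat <- estimate_fdr_q(rh)$q_hat
  rownames(out) <- NULL
  out
}

#' Collapse annotations to unique structures
#'
#' Multiple hits (different runs, adducts) can annotate the same 2D
#' structure; the hit with the highest confidence represents each
#' structure. Ties resolve to the lexicographically smallest hit id.
#'
#' @param annotations data.frame with columns `structure_key` and
#'   `confidence` (e.g. output of [run_score_pipeline()]).
#' @return One row per distinct structure, sorted by descending
#'   confidence.
#' @export
dedupe_by_structure <- function(annotations) {
  if (!all(c("structure_key", "confidence") %in% names(annotations)))
    stop("annotations must have columns structure_key and confidence")
  if (nrow(annotations) == 0) return(annotations)
  key <- if ("hit_id" %in% names(annotations))
    as.character(annotations$hit_id) else seq_len(nrow(annotations))
  ord <- order(annotations$structure_key, -annotations$confidence, key)
  a <- annotations[ord, , drop = FALSE]
  a <- a[!duplicated(a$structure_key), , drop = FALSE]
  a <- a[order(-a$confidence, a$structure_key), , drop = FALSE]
  rownames(a) <- NULL
  a
}
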
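# L2-regularized squared-hinge linear SVM:
#   min_{w,b} 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i (x_i.w + b))^2
# Solved by an active-set Newton iteration (the objective is convex and
# piecewise quadratic, so each Newton step solves a ridge-like system on
# the margin-violating samples), with a backtracking safeguard.
fit_l2svm <- function(X, y, C, max_iter = 200, tol = 1e-12) {
  X <- as.matrix(X)
  d <- ncol(X)
  Xb <- cbind(X, 1)
  reg <- diag(c(rep(1, d), 1e-12))  # bias effectively unregularized
  obj <- function(theta) {
    s <- pmax(0, 1 - y * drop(Xb %*% theta))
    0.5 * sum(theta[seq_len(d)]^2) + C * sum(s^2)
  }
  theta <- rep(0, d + 1)
  f_cur <- obj(theta)
  for (it in seq_len(max_iter)) {
    act <- y * drop(Xb %*% theta) < 1
    if (!any(act)) break
    Xa <- Xb[act, , drop = FALSE]
    H <- reg + 2 * C * crossprod(Xa)
    rhs <- 2 * C * crossprod(Xa, y[act])
    cand <- tryCatch(drop(solve(H, rhs)), error = function(e) NULL)
    if (is.null(cand)) break
    # backtrack along the segment towards the Newton point
    step <- 1
    repeat {
      trial <- theta + step * (cand - theta)
      f_trial <- obj(trial)
      if (f_trial <= f_cur + 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    if (f_trial > f_cur) break
    converged <- f_cur - f_trial < tol * (1 + abs(f_cur))
    theta <- trial
    f_cur <- f_trial
    if (converged) break
  }
  list(w = unname(theta[seq_len(d)]), b = unname(theta[d + 1]),
       objective = f_cur)
}

augment_directional <- function(Xs, y, schema, feature_names, beta) {
  dirs <- schema$direction[match(feature_names, schema$name)]
  constrained <- which(!is.na(dirs) & dirs != 0)
  if (length(constrained) == 0) return(list(X = Xs, y = y))
  Xa <- matrix(0, nrow = length(constrained), ncol = ncol(Xs))
  for (k in seq_along(constrained)) {
    j <- constrained[k]
    Xa[k, j] <- dirs[j] * beta
  }
  list(X = rbind(Xs, Xa), y = c(y, rep(1, length(constrained))))
}

#' Train a sign-constrained linear SVM confidence model
#'
#' Fits an L2-regularized squared-hinge linear SVM on standardized, capped
#' hit features, enforcing the directionality declared in the schema: for
#' every feature with direction `d_j != 0`, one synthetic positive training
#' sample is added whose only non-zero entry is `d_j * beta` on feature
#' `j`. For large `beta` any optimal solution must satisfy
#' `w_j * d_j >= 0` (up to a margin of order `1/beta`), so directionality
#' is obtained with an ordinary SVM solver and the exact value of `beta`
#' is immaterial. The regularization constant `C` is selected from
#' `C_grid` by internal cross-validation; decision values are mapped to
#' posterior estimates by [platt_fit()].
#'
#' @param X data.frame or matrix of feature values (columns named as in
#'   `schema`). Rows with `NA` features are rejected; drop
#'   multiple-candidate features first for the single-candidate regime
#'   (done automatically when `regime = "single"`).
#' @param labels Logical (or `"correct"`/`"incorrect"`) vector: is the hit
#'   correct?
#' @param schema A [feature_schema()].
#' @param C_grid Candidate regularization constants; default
#'   `10^(-5:5)`.
#' @param beta Augmentation magnitude; default `1e7`.
#' @param nfolds Folds for the internal C selection (default 5).
#' @param collision_energy Tag (10, 20, 40 or `"merged"`) recorded for
#'   [select_model()].
#' @param regime `"multi"` or `"single"` candidate-count regime.
#' @return Object of class `confidence_model` with elements `weights`,
#'   `bias`, `center`, `scale`, `cap_min`, `cap_max`, `platt` (A, B), `C`,
#'   `beta`, `collision_energy`, `regime`, `schema`.
#' @export
train_directional_svm <- function(X, labels, schema = default_feature_schema(),
                                  C_grid = 10^(-5:5), beta = 1e7,
                                  nfolds = 5, collision_energy = NA,
                                  regime = c("multi", "single")) {
  regime <- match.arg(regime)
  if (!inherits(schema, "feature_schema")) stop("schema must be a feature_schema")
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "correct"
  y <- ifelse(as.logical(labels), 1, -1)
  if (length(unique(y)) < 2)
    stop("training data must contain both correct and incorrect hits")
  X <- as.data.frame(X)
  keep <- intersect(schema$name, colnames(X))
  if (regime == "single")
    keep <- setdiff(keep,
                    schema$name[schema$requires_multiple_candidates])
  if (length(keep) == 0) stop("no schema features present in X")
  X <- as.matrix(X[, keep, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X))
    stop("feature matrix contains NA; incomplete rows must be handled ",
         "upstream (single-candidate regime?)")
  cap_min <- apply(X, 2, min)
  cap_max <- apply(X, 2, max)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")

  fit_with_aug <- function(Xtr, ytr, C) {
    aug <- augment_directional(Xtr, ytr, schema, keep, beta)
    fit_l2svm(aug$X, aug$y, C)
  }

  C_grid <- sort(C_grid)
  best_C <- C_grid[1]
  if (length(C_grid) > 1) {
    n <- nrow(Xs)
    folds <- rep_len(seq_len(nfolds), n)[sample.int(n)]
    acc <- vapply(C_grid, function(C) {
      correct <- 0
      for (k in seq_len(nfolds)) {
        tr <- folds != k
        if (length(unique(y[tr])) < 2) next
        fit <- fit_with_aug(Xs[tr, , drop = FALSE], y[tr], C)
        f <- drop(Xs[!tr, , drop = FALSE] %*% fit$w) + fit$b
        correct <- correct + sum(sign(f) == y[!tr])
      }
      correct / n
    }, numeric(1))
    best_C <- C_grid[which.max(acc)]  # ties resolve to the smallest C
  }
  fit <- fit_with_aug(Xs, y, best_C)
  f <- drop(Xs %*% fit$w) + fit$b
  platt <- platt_fit(f, y > 0)
  structure(list(
    weights = stats::setNames(fit$w, keep), bias = fit$b,
    center = center, scale = scale, cap_min = cap_min, cap_max = cap_max,
    platt = platt, C = best_C, beta = beta,
    collision_energy = collision_energy, regime = regime,
    schema = schema[match(keep, schema$name), , drop = FALSE]),
    class = "confidence_model")
}

#' @export
print.confidence_model <- function(x, ...) {
  cat(sprintf("confidence_model (%s regime, CE %s): C = %g, A = %.4g, B = %.4g\n",
              x$regime, as.character(x$collision_energy), x$C,
              x$platt$A, x$platt$B))
  print(round(x$weights, 5))
  invisible(x)
}

#' Fit Platt scaling parameters by penalized maximum likelihood
#'
#' Estimates `(A, B)` of the sigmoid `P(correct | f) = 1 / (1 + exp(A f +
#' B))` by Newton iteration on the cross-entropy, using the standard
#' prior-corrected targets `(n_pos + 1) / (n_pos + 2)` and
#' `1 / (n_neg + 2)` that keep the fit finite under perfect separation.
#'
#' @param f Numeric decision values.
#' @param labels Logical: positive class membership.
#' @param max_iter,min_step,sigma Newton iteration controls.
#' @return List with `A` and `B`. When all decision values are equal the
#'   slope is fixed at 0 and only `B` is fitted (with a warning).
#' @export
platt_fit <- function(f, labels, max_iter = 100, min_step = 1e-10,
                      sigma = 1e-12) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2) stop("both classes required for Platt scaling")
  n_pos <- sum(y); n_neg <- sum(!y)
  t <- ifelse(y, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  if (stats::sd(f) == 0) {
    warning("degenerate decision values; fitting intercept only")
    p <- mean(t)
    return(list(A = 0, B = log((1 - p) / p)))
  }
  fval <- function(A, B) {
    fApB <- f * A + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  fv <- fval(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- f * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sum(f^2 * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    d1 <- t - p
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      newA <- A + step * dA
      newB <- B + step * dB
      newf <- fval(newA, newB)
      if (newf < fv + 1e-4 * step * gd) {
        A <- newA; B <- newB; fv <- newf
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  list(A = A, B = B)
}

#' Confidence score of hit features under a trained model
#'
#' Applies capping and standardization, computes the decision value
#' `f = w . x + b` and returns the Platt-scaled value
#' `1 / (1 + exp(A f + B))`. The result orders hits by how likely they are
#' to be correct but must not be read as a calibrated probability.
#'
#' @param model A [train_directional_svm()] model.
#' @param features Named numeric vector or data.frame (one row per hit).
#'   A multi-candidate model refuses feature rows whose
#'   multiple-candidate features are missing (`NA`): use the
#'   single-candidate model for those queries (see [select_model()]).
#' @return Numeric vector of confidence scores in (0, 1).
#' @export
confidence_score <- function(model, features) {
  if (!inherits(model, "confidence_model"))
    stop("model must be a confidence_model")
  X <- as_feature_matrix(features, names(model$weights))
  if (anyNA(X))
    stop("features contain NA for a ", model$regime,
         "-candidate model; select the matching regime model")
  Xs <- standardize_and_cap(X, model)
  f <- unname(drop(Xs %*% model$weights)) + model$bias
  1 / (1 + exp(model$platt$A * f + model$platt$B))
}

#' Decision value (uncalibrated margin) of hit features
#' @inheritParams confidence_score
#' @return Numeric vector `w . x + b`.
#' @export
decision_value <- function(model, features) {
  X <- standardize_and_cap(as_feature_matrix(features, names(model$weights)),
                           model)
  unname(drop(X %*% model$weights)) + model$bias
}

#' Select the appropriate confidence model from a registry
#'
#' Picks the model of the matching candidate-count regime whose collision
#' energy is closest to the query's (e.g. the 40 eV model for a 35 eV
#' query); "merged" queries take the "merged" model. Energy ties resolve
#' to the lower energy.
#'
#' @param registry List of `confidence_model` objects.
#' @param collision_energy Query collision energy (numeric eV or
#'   `"merged"`).
#' @param n_candidates Number of candidates for the query; 1 selects the
#'   single-candidate regime.
#' @return A `confidence_model`.
#' @export
select_model <- function(registry, collision_energy, n_candidates) {
  if (length(registry) == 0) stop("empty model registry")
  regime <- if (n_candidates <= 1) "single" else "multi"
  pool <- Filter(function(m) m$regime == regime, registry)
  if (length(pool) == 0)
    stop("no model for the ", regime, "-candidate regime in the registry")
  ce <- lapply(pool, function(m) m$collision_energy)
  if (identical(collision_energy, "merged")) {
    hit <- which(vapply(ce, identical, logical(1), "merged"))
    if (length(hit)) return(pool[[hit[1]]])
    stop("no merged-spectra model in the registry")
  }
  num <- vapply(ce, function(e)
    if (is.numeric(e)) e else NA_real_, numeric(1))
  if (all(is.na(num)))
    stop("no model with a numeric collision energy in the registry")
  d <- abs(num - as.numeric(collision_energy))
  cand <- which(d == min(d, na.rm = TRUE))
  pool[[cand[which.min(num[cand])]]]
}

#' Write / read a confidence model as JSON
#'
#' All quantities needed to reproduce scoring — weights, bias,
#' standardization statistics, training caps, Platt parameters, energy and
#' regime tags, schema — are persisted.
#'
#' @param model A `confidence_model`.
#' @param path File path.
#' @return `write_confidence_model` invisibly returns `path`;
#'   `read_confidence_model` returns the model.
#' @export
write_confidence_model <- function(model, path) {
  obj <- list(
    format = "confmet_model", version = 1L,
    weights = as.list(model$weights), bias = model$bias,
    center = as.list(model$center), scale = as.list(model$scale),
    cap_min = as.list(model$cap_min), cap_max = as.list(model$cap_max),
    platt = model$platt, C = model$C, beta = model$beta,
    collision_energy = model$collision_energy, regime = model$regime,
    schema = as.data.frame(model$schema))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_confidence_model
#' @export
read_confidence_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "confmet_model"))
    stop("not a confmet model file: ", path)
  sc <- obj$schema
  schema <- feature_schema(sc$name, sc$direction,
                           sc$requires_multiple_candidates, sc$db_specific)
  ce <- obj$collision_energy
  if (is.character(ce) && ce != "merged") ce <- as.numeric(ce)
  structure(list(
    weights = unlist(obj$weights), bias = obj$bias,
    center = unlist(obj$center), scale = unlist(obj$scale),
    cap_min = unlist(obj$cap_min), cap_max = unlist(obj$cap_max),
    platt = obj$platt, C = obj$C, beta = obj$beta,
    collision_energy = ce, regime = obj$regime, schema = schema),
    class = "confidence_model")
}

# Reference solver used in tests: projected (sub)gradient descent on the
# explicitly sign-constrained squared-hinge SVM. Independent of the
# augmentation route used by train_directional_svm().
svm_signconstrained_pg <- function(X, y, C, directions, n_iter = 20000,
                                   lr = NULL) {
  X <- as.matrix(X)
  d <- ncol(X)
  # step below 1/L, L a Frobenius upper bound on the gradient Lipschitz
  # constant of the squared-hinge objective (bias column included)
  if (is.null(lr)) lr <- 1 / (1 + 2 * C * (sum(X^2) + nrow(X)))
  w <- rep(0, d); b <- 0
  proj <- function(w) {
    up <- directions > 0; dn <- directions < 0
    w[up] <- pmax(w[up], 0)
    w[dn] <- pmin(w[dn], 0)
    w
  }
  for (it in seq_len(n_iter)) {
    f <- drop(X %*% w) + b
    s <- pmax(0, 1 - y * f)
    grad_w <- w - 2 * C * drop(crossprod(X, y * s))
    grad_b <- -2 * C * sum(y * s)
    w <- proj(w - lr * grad_w)
    b <- b - lr * grad_b
  }
  list(w = unname(w), b = unname(b))
}
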
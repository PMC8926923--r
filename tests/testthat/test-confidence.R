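toy_separable <- function(n = 60) {
  # two features, both genuinely positive for the positive class
  y <- rep(c(TRUE, FALSE), each = n / 2)
  data.frame(a = ifelse(y, 2, -2) + rnorm(n, 0, 0.2),
             b = ifelse(y, 1, -1) + rnorm(n, 0, 0.2),
             correct = y)
}

test_that("feature extraction restricts to the hit formula and finds gaps", {
  cands <- data.frame(candidate_id = c("x", "y"), score = c(10, 7))
  fx <- extract_features(cands)
  expect_equal(unname(fx$features[["score_gap_runner_up"]]), 3)
  expect_equal(fx$hit$candidate_id, "x")

  single <- extract_features(data.frame(candidate_id = "x", score = 5))
  expect_true(is.na(single$features[["score_gap_runner_up"]]))
  expect_true(is.na(single$features[["log_num_candidates"]]))
  expect_equal(single$n_candidates, 1)

  mixed <- data.frame(candidate_id = paste0("c", 1:5),
                      score = c(9, 8, 7, 6, 5),
                      formula = c("C6H6", "C5H10O", "C6H6", "C6H6", "C5H10O"))
  fx2 <- extract_features(mixed)
  expect_equal(fx2$n_candidates, 3)  # only the hit-formula candidates
  expect_equal(unname(fx2$features[["log_num_candidates"]]), log(3))
  expect_equal(unname(fx2$features[["score_gap_runner_up"]]), 9 - 7)

  # deterministic tie-break by candidate id
  tie <- data.frame(candidate_id = c("b", "a"), score = c(4, 4))
  expect_equal(extract_features(tie)$hit$candidate_id, "a")
  expect_error(extract_features(data.frame(candidate_id = character(),
                                           score = numeric())), "empty")

  set.seed(5)
  u1 <- extract_features(mixed, select = "uniform")$hit$candidate_id
  set.seed(5)
  u2 <- extract_features(mixed, select = "uniform")$hit$candidate_id
  expect_identical(u1, u2)
})

test_that("capping then standardizing equals the composed elementary maps", {
  set.seed(12)
  df <- toy_separable(80)
  m <- train_directional_svm(df[, c("a", "b")], df$correct,
                             schema = feature_schema(c("a", "b"), c(1L, 1L)),
                             C_grid = 1)
  # at the training mean the standardized value is 0
  at_mean <- m$center
  expect_equal(unname(standardize_and_cap(at_mean, m)[1, ]), c(0, 0),
               tolerance = 1e-12)
  # values above the cap behave exactly like the cap
  over <- c(a = m$cap_max[["a"]] + 100, b = 0)
  at_cap <- c(a = m$cap_max[["a"]], b = 0)
  expect_equal(standardize_and_cap(over, m), standardize_and_cap(at_cap, m))
  # random vectors: composition of clip and z-score
  for (i in 1:20) {
    v <- c(a = rnorm(1, 0, 10), b = rnorm(1, 0, 10))
    manual <- (pmin(pmax(v, m$cap_min), m$cap_max) - m$center) / m$scale
    expect_equal(unname(standardize_and_cap(v, m)[1, ]), unname(manual),
                 tolerance = 1e-12)
  }
  # scoring a capped vector twice equals scoring once
  capped <- pmin(pmax(c(a = 50, b = -50), m$cap_min), m$cap_max)
  expect_equal(confidence_score(m, capped),
               confidence_score(m, pmin(pmax(capped, m$cap_min), m$cap_max)))
})

test_that("directional SVM separates toy data with compliant weights", {
  set.seed(21)
  df <- toy_separable(60)
  m <- train_directional_svm(df[, c("a", "b")], df$correct,
                             schema = feature_schema(c("a", "b"), c(1L, 1L)),
                             C_grid = 10^(-2:2))
  expect_true(all(m$weights >= -1e-9))
  f <- decision_value(m, df[, c("a", "b")])
  expect_equal(mean((f > 0) == df$correct), 1)
})

test_that("enforced directionality matches a projected-gradient oracle", {
  set.seed(31)
  n <- 200
  x1 <- rnorm(n)
  y <- runif(n) < plogis(2 * x1)
  x2 <- -1.0 * as.numeric(y) + rnorm(n, 0, 0.5)  # anti-correlated feature
  X <- data.frame(a = x1, b = x2)

  unres <- train_directional_svm(X, y,
                                 schema = feature_schema(c("a", "b"),
                                                         c(0L, 0L)),
                                 C_grid = 1)
  expect_lt(unres$weights[["b"]], 0)

  for (C in c(0.1, 1, 10)) {
    con <- train_directional_svm(X, y,
                                 schema = feature_schema(c("a", "b"),
                                                         c(1L, 1L)),
                                 C_grid = C)
    expect_gte(con$weights[["b"]], -1e-9)
    Xs <- sweep(sweep(as.matrix(X), 2, con$center), 2, con$scale, "/")
    pg <- confmet:::svm_signconstrained_pg(Xs, ifelse(y, 1, -1), C,
                                           c(1, 1), n_iter = 60000)
    expect_equal(unname(con$weights), pg$w, tolerance = 1e-3)
    expect_equal(con$bias, pg$b, tolerance = 1e-3)
  }
})

test_that("the augmentation magnitude beta is immaterial", {
  d <- gen_hit_dataset(300, seed = 41)
  multi <- d[d$n_candidates > 1, ]
  X <- feature_cols(multi)
  ws <- lapply(c(1e7, 1e8, 1e9), function(beta) {
    set.seed(1)
    train_directional_svm(X, multi$correct, C_grid = 1,
                          beta = beta)$weights
  })
  scale_ref <- max(abs(ws[[1]]))
  expect_lt(max(abs(ws[[1]] - ws[[2]])) / scale_ref, 1e-4)
  expect_lt(max(abs(ws[[1]] - ws[[3]])) / scale_ref, 1e-4)
})

test_that("trained models respect every declared direction", {
  d <- gen_hit_dataset(500, seed = 51)
  multi <- d[d$n_candidates > 1, ]
  set.seed(2)
  m <- train_directional_svm(feature_cols(multi), multi$correct,
                             C_grid = 10^(-3:3))
  dirs <- m$schema$direction
  expect_true(all(m$weights * dirs >= -1e-9))
  expect_error(train_directional_svm(feature_cols(multi),
                                     rep(TRUE, nrow(multi))),
               "both correct and incorrect")
})

test_that("Platt scaling agrees with a logistic-regression oracle", {
  # the sigmoid with A = 0, B = 0 is the constant 1/2
  expect_equal(1 / (1 + exp(0 * 3.7 + 0)), 0.5)

  set.seed(61)
  f <- c(rnorm(400, 1.2), rnorm(400, -1.2))
  lab <- rep(c(TRUE, FALSE), each = 400)
  pl <- platt_fit(f, lab)
  g <- glm(lab ~ f, family = binomial)
  se <- summary(g)$coefficients[, "Std. Error"]
  # P(correct|f) = 1/(1+exp(Af+B)) corresponds to glm slope -A, intercept -B
  expect_lt(abs(-pl$A - coef(g)[["f"]]), 4 * se[["f"]])
  expect_lt(abs(-pl$B - coef(g)[["(Intercept)"]]), 4 * se[["(Intercept)"]])

  sep <- platt_fit(c(1, 2, 3, -1, -2, -3), c(TRUE, TRUE, TRUE,
                                             FALSE, FALSE, FALSE))
  p <- 1 / (1 + exp(sep$A * c(1, 2, 3) + sep$B))
  expect_true(all(p > 0.5))

  expect_warning(deg <- platt_fit(rep(1, 10), rep(c(TRUE, FALSE), 5)),
                 "degenerate")
  expect_equal(deg$A, 0)
  expect_error(platt_fit(1:5, rep(TRUE, 5)), "both classes")
})

test_that("confidence scores are monotone Platt maps of decision values", {
  set.seed(71)
  df <- toy_separable(80)
  m <- train_directional_svm(df[, c("a", "b")], df$correct,
                             schema = feature_schema(c("a", "b"), c(1L, 1L)),
                             C_grid = 1)
  expect_lt(m$platt$A, 0)  # higher decision value, higher confidence
  f <- decision_value(m, df[, c("a", "b")])
  sc <- confidence_score(m, df[, c("a", "b")])
  expect_true(all(sc > 0 & sc < 1))
  expect_equal(order(f), order(sc))
  # batch scoring equals per-item scoring
  per_item <- vapply(seq_len(nrow(df)), function(i)
    confidence_score(m, df[i, c("a", "b")]), numeric(1))
  expect_equal(sc, per_item)
  # a decision value with A f + B = 0 maps to exactly 0.5
  f0 <- -m$platt$B / m$platt$A
  x0 <- c(a = 0, b = 0)
  # invert the standardization to land on decision value f0
  x0["a"] <- m$center[["a"]] +
    m$scale[["a"]] * (f0 - m$bias) / m$weights[["a"]]
  x0["a"] <- min(max(x0["a"], m$cap_min[["a"]]), m$cap_max[["a"]])
  x0["b"] <- m$center[["b"]]
  if (abs(decision_value(m, x0) - f0) < 1e-9)
    expect_equal(confidence_score(m, x0), 0.5, tolerance = 1e-6)
})

test_that("model selection picks nearest energy and right regime", {
  mk <- function(ce, regime) {
    d <- gen_hit_dataset(120, seed = 81)
    if (regime == "multi") d <- d[d$n_candidates > 1, ]
    X <- feature_cols(d)
    if (regime == "single")
      X <- X[, !default_feature_schema()$requires_multiple_candidates]
    set.seed(3)
    train_directional_svm(X, d$correct, C_grid = 1,
                          collision_energy = ce, regime = regime)
  }
  reg <- list(mk(10, "multi"), mk(20, "multi"), mk(40, "multi"),
              mk("merged", "multi"), mk(20, "single"))
  expect_equal(select_model(reg, 35, 5)$collision_energy, 40)
  expect_equal(select_model(reg, 20, 5)$collision_energy, 20)
  expect_equal(select_model(reg, "merged", 5)$collision_energy, "merged")
  expect_equal(select_model(reg, 20, 1)$regime, "single")
  expect_error(select_model(list(), 20, 5), "empty")
  # multi-candidate models refuse incomplete feature rows
  d1 <- gen_hit_dataset(50, seed = 82, p_single = 1)
  expect_error(confidence_score(reg[[1]], feature_cols(d1)[1, ]), "NA")
})

test_that("models survive a JSON round trip", {
  d <- gen_hit_dataset(200, seed = 91)
  multi <- d[d$n_candidates > 1, ]
  set.seed(4)
  m <- train_directional_svm(feature_cols(multi), multi$correct,
                             C_grid = 1, collision_energy = 20)
  p <- tempfile(fileext = ".json")
  write_confidence_model(m, p)
  m2 <- read_confidence_model(p)
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$platt, m$platt, tolerance = 1e-12)
  expect_equal(m2$collision_energy, 20)
  X <- feature_cols(multi)[1:10, ]
  expect_equal(confidence_score(m2, X), confidence_score(m, X),
               tolerance = 1e-12)
})
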
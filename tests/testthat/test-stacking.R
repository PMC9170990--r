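make_feature_data <- function(n = 60, p = 30, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1:3] <- X[, 1:3] + 1.5 * y
  list(X = X, y = y)
}

test_that("meta input width is 3 base scores plus the selected features", {
  d <- make_feature_data()
  model <- stack_fit(d$X, d$y, config = small_stack_config(), seed = 1)
  n_sel <- length(model$selector$selected_indices)
  expect_equal(length(model$meta_weights), 1 + 3 + n_sel)  # + intercept
  prob <- stack_predict(model, d$X)
  expect_true(all(prob > 0 & prob < 1))
})

test_that("zero meta weights give probability one half everywhere", {
  d <- make_feature_data()
  model <- stack_fit(d$X, d$y, config = small_stack_config(), seed = 1)
  model$meta_weights[] <- 0
  expect_equal(stack_predict(model, d$X), rep(0.5, nrow(d$X)))
})

test_that("out-of-fold scores come only from models that never saw the row", {
  d <- make_feature_data(n = 60)
  cfg <- small_stack_config()
  model <- stack_fit(d$X, d$y, config = cfg, seed = 7)
  Xs <- lasso_transform(model$selector, d$X)
  for (f in seq_len(cfg$oof_folds)) {
    tr <- model$folds != f
    refit <- sucstack:::fit_base_learners(
      Xs[tr, , drop = FALSE], d$y[tr], cfg,
      seed = sucstack:::derive_seed(model$seed, paste0("fold", f)))
    rescored <- sucstack:::score_base_learners(refit, Xs[!tr, , drop = FALSE])
    expect_equal(unname(model$oof_scores[!tr, ]), unname(rescored),
                 tolerance = 1e-12)
  }
})

test_that("predictions are a pure function of model and input", {
  d <- make_feature_data()
  model <- stack_fit(d$X, d$y, config = small_stack_config(), seed = 2)
  X_dup <- d$X[c(1, 1, 5, 5), , drop = FALSE]
  prob <- stack_predict(model, X_dup)
  expect_equal(prob[1], prob[2])
  expect_equal(prob[3], prob[4])
})

test_that("meta probability is monotone in a positively weighted base score", {
  d <- make_feature_data()
  model <- stack_fit(d$X, d$y, config = small_stack_config(), seed = 3)
  w <- model$meta_weights
  Xs <- lasso_transform(model$selector, d$X)
  meta_x <- cbind(sucstack:::score_base_learners(model$base_models, Xs), Xs)
  p0 <- plogis(w[1] + meta_x %*% w[-1])
  for (j in 1:3) {
    if (w[1 + j] <= 0) next
    bumped <- meta_x
    bumped[, j] <- bumped[, j] + 0.05
    p1 <- plogis(w[1] + bumped %*% w[-1])
    expect_true(all(p1 >= p0))
  }
})

test_that("the whole ensemble is deterministic given seed and data", {
  d <- make_feature_data(n = 40)
  m1 <- stack_fit(d$X, d$y, config = small_stack_config(), seed = 11)
  m2 <- stack_fit(d$X, d$y, config = small_stack_config(), seed = 11)
  expect_equal(stack_predict(m1, d$X), stack_predict(m2, d$X),
               tolerance = 1e-12)
})

test_that("in-sample scoring mode is available for protocol comparison", {
  d <- make_feature_data()
  model <- stack_fit(d$X, d$y, config = small_stack_config(oof = FALSE),
                     seed = 1)
  expect_equal(model$oof_folds, 0L)
  expect_true(all(is.finite(stack_predict(model, d$X))))
})

test_that("degenerate inputs are rejected", {
  d <- make_feature_data(n = 24)
  expect_error(stack_fit(d$X[1:10, ], d$y[1:10]), "at least 20")
  expect_error(stack_fit(d$X, rep(1, 24)), "both classes")
  model <- stack_fit(d$X, d$y, config = small_stack_config(), seed = 1)
  expect_error(stack_predict(model, d$X[, 1:5]), "columns")
})
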
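# Base learners of the stacking ensemble. Each fit_* returns an object
# with a predict_* companion emitting scores in [0, 1].

# linear SVM with deterministic sigmoid (Platt) calibration fitted on the
# training decision values
fit_svm_platt <- function(X, y, C = 1, gamma = 1, kernel = "linear") {
  yf <- factor(y, levels = c(0, 1))
  fit <- e1071::svm(x = X, y = yf, kernel = kernel, cost = C, gamma = gamma,
                    scale = FALSE)
  dv <- as.numeric(attr(predict(fit, X, decision.values = TRUE),
                        "decision.values"))
  # the logistic slope absorbs libsvm's pairwise sign convention
  platt <- suppressWarnings(glm(y ~ dv, family = binomial()))
  list(svm = fit, platt = coef(platt))
}

predict_svm_platt <- function(model, X) {
  dv <- as.numeric(attr(predict(model$svm, X, decision.values = TRUE),
                        "decision.values"))
  as.numeric(plogis(model$platt[1L] + model$platt[2L] * dv))
}

# gradient-boosted trees grown leaf-wise (LightGBM-style), via xgboost
fit_gbdt <- function(X, y, learning_rate = 0.27, max_depth = 40,
                     num_leaves = 51, n_estimators = 587) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "binary:logistic",
      learning_rate = learning_rate,
      max_depth = as.integer(max_depth),
      max_leaves = as.integer(num_leaves),
      grow_policy = "lossguide",
      tree_method = "hist",
      nthread = 1
    ),
    data = dtrain,
    nrounds = as.integer(n_estimators),
    verbose = 0
  )
}

predict_gbdt <- function(model, X) {
  as.numeric(predict(model, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1)))
}

fit_base_learners <- function(X, y, config, seed) {
  list(
    svm = do.call(fit_svm_platt, c(list(X = X, y = y), config$svm)),
    bls = bls_fit(X, y, config = do.call(bls_config, config$bls),
                  seed = derive_seed(seed, "base_bls")),
    gbdt = do.call(fit_gbdt, c(list(X = X, y = y), config$gbdt))
  )
}

score_base_learners <- function(models, X) {
  cbind(svm = predict_svm_platt(models$svm, X),
        bls = bls_score(models$bls, X),
        gbdt = predict_gbdt(models$gbdt, X))
}
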
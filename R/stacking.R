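#' Stacking ensemble configuration
#'
#' Defaults are the tuned hyperparameters used throughout the package:
#' linear SVM (C = 1, gamma = 1), leaf-wise boosted trees (learning rate
#' 0.27, max depth 40, 51 leaves, 587 rounds), the default broad learning
#' system, internal stratified 5-fold out-of-fold score generation, and a
#' cross-validated LASSO penalty.
#'
#' @param svm list of SVM settings (`kernel`, `C`, `gamma`).
#' @param gbdt list of boosted-tree settings (`learning_rate`,
#'   `max_depth`, `num_leaves`, `n_estimators`).
#' @param bls list of [bls_config()] arguments.
#' @param oof if `TRUE` (default) the meta-learner is trained on
#'   out-of-fold base scores; if `FALSE` it sees in-sample scores (the
#'   leakier construction, provided for protocol comparison).
#' @param oof_folds internal stratified folds used to build the
#'   out-of-fold scores.
#' @param lasso_lambda penalty passed to [fit_lasso()] (default `"cv"`).
#' @return list of class `stack_config`.
#' @export
stack_config <- function(svm = list(kernel = "linear", C = 1, gamma = 1),
                         gbdt = list(learning_rate = 0.27, max_depth = 40,
                                     num_leaves = 51, n_estimators = 587),
                         bls = list(),
                         oof = TRUE, oof_folds = 5,
                         lasso_lambda = "cv") {
  structure(list(svm = svm, gbdt = gbdt, bls = bls, oof = oof,
                 oof_folds = as.integer(oof_folds),
                 lasso_lambda = lasso_lambda),
            class = "stack_config")
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k)
    stop("each class needs at least ", k, " members for ", k, " folds")
  with_seed(seed, {
    unsplit(lapply(split(seq_along(y), y), function(ix)
      sample(rep_len(seq_len(k), length(ix)))), y)
  })
}

#' Fit the two-layer stacking ensemble
#'
#' Fits the LASSO selector on the full feature matrix, reduces it, builds
#' out-of-fold base-learner scores (linear SVM, broad learning system,
#' boosted trees) through an internal stratified K-fold so that no
#' meta-training row is scored by a base model that saw it, fits a
#' weakly L2-penalized logistic meta-learner on the spliced vector
#' [scores, selected features], and refits the three base learners on the
#' full reduced data for inference.
#'
#' @param X numeric feature matrix (n x p, 811 columns for the fused
#'   encoding).
#' @param y binary labels in `{0, 1}` (or the label factor).
#' @param config a [stack_config()].
#' @param seed seed controlling fold assignment and the BLS weights.
#' @param selector optionally, a pre-fitted [fit_lasso()] selector (used
#'   by the global-selection protocol where selection happens once,
#'   outside cross-validation); default fits one on `(X, y)`.
#' @return object of class `stacking_model`.
#' @export
stack_fit <- function(X, y, config = stack_config(), seed = 1,
                      selector = NULL) {
  X <- as.matrix(X)
  y <- if (is.factor(y)) as.integer(y == levels(y)[2L]) else as.numeric(y)
  if (nrow(X) < 20) stop("need at least 20 samples")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (is.null(selector))
    selector <- fit_lasso(X, y, lambda = config$lasso_lambda,
                          seed = derive_seed(seed, "lasso"),
                          min_features = 1)
  Xs <- lasso_transform(selector, X)

  if (config$oof) {
    folds <- stratified_folds(y, config$oof_folds,
                              derive_seed(seed, "oof_folds"))
    scores <- matrix(NA_real_, nrow(Xs), 3L,
                     dimnames = list(NULL, c("svm", "bls", "gbdt")))
    for (f in seq_len(config$oof_folds)) {
      tr <- folds != f
      models_f <- fit_base_learners(Xs[tr, , drop = FALSE], y[tr], config,
                                    seed = derive_seed(seed, paste0("fold", f)))
      scores[!tr, ] <- score_base_learners(models_f, Xs[!tr, , drop = FALSE])
    }
  } else {
    folds <- NULL
    full0 <- fit_base_learners(Xs, y, config,
                               seed = derive_seed(seed, "full"))
    scores <- score_base_learners(full0, Xs)
  }

  meta_x <- cbind(scores, Xs)
  meta <- glmnet::glmnet(meta_x, y, family = "binomial", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
  meta_weights <- as.numeric(coef(meta, s = 1e-4))

  base_models <- fit_base_learners(Xs, y, config,
                                   seed = derive_seed(seed, "full"))
  structure(list(selector = selector, base_models = base_models,
                 meta_weights = meta_weights, config = config,
                 oof_folds = if (config$oof) config$oof_folds else 0L,
                 folds = folds, oof_scores = scores, seed = seed,
                 p_in = ncol(X)),
            class = "stacking_model")
}

#' Predict succinylation probabilities with a fitted stacking ensemble
#'
#' Reduces the input through the stored selector, scores it with the three
#' refitted base learners, and applies the logistic meta-learner to the
#' spliced vector [base scores, selected features].
#'
#' @param model fitted [stack_fit()] object.
#' @param X numeric matrix with the training dimensionality.
#' @return numeric vector of probabilities in `(0, 1)`; the positive call
#'   threshold is 0.5.
#' @export
stack_predict <- function(model, X) {
  stopifnot(inherits(model, "stacking_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$p_in)
    stop("X has ", ncol(X), " columns; model was fitted on ", model$p_in)
  Xs <- lasso_transform(model$selector, X)
  meta_x <- cbind(score_base_learners(model$base_models, Xs), Xs)
  as.numeric(plogis(model$meta_weights[1L] +
                      meta_x %*% model$meta_weights[-1L]))
}
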
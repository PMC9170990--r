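#' Classification metrics from confusion counts
#'
#' Computes sensitivity, specificity, accuracy, Matthews correlation
#' coefficient and F1 score. An MCC denominator of zero yields MCC = 0; an
#' F1 denominator of zero yields F1 = 0.
#'
#' @param TP,TN,FP,FN nonnegative confusion counts.
#' @return named numeric vector `(Sn, Sp, Acc, MCC, F1)`.
#' @export
#' @examples
#' compute_metrics(TP = 8, TN = 7, FP = 3, FN = 2)
compute_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  Sn <- if (TP + FN > 0) TP / (TP + FN) else 0
  Sp <- if (TN + FP > 0) TN / (TN + FP) else 0
  Acc <- (TP + TN) / sum(counts)
  denom <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  MCC <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  F1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  c(Sn = Sn, Sp = Sp, Acc = Acc, MCC = MCC, F1 = F1)
}

#' ROC curve and AUC
#'
#' AUC is computed by the rank statistic (midranks for ties), which equals
#' the trapezoidal area under the ROC curve.
#'
#' @param scores numeric prediction scores (larger = more positive).
#' @param labels binary labels in `{0, 1}` (or the label factor).
#' @return list with `auc` and `curve` (data frame of `fpr`, `tpr` sorted
#'   along the curve).
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels == levels(labels)[2L])
       else as.integer(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1) / n_pos)
  fpr <- c(0, cumsum(y[ord] == 0) / n_neg)
  list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
}

# confusion counts at a probability threshold
confusion_counts <- function(prob, y, threshold = 0.5) {
  call <- as.integer(prob >= threshold)
  c(TP = sum(call == 1 & y == 1), TN = sum(call == 0 & y == 0),
    FP = sum(call == 1 & y == 0), FN = sum(call == 0 & y == 1))
}

#' Stratified K-fold cross-validation of the full pipeline
#'
#' The data are partitioned into stratified shuffled folds; for each fold
#' the entire pipeline — CBOW embedding training, encoding, LASSO
#' selection, base learners and meta-learner — is refitted on the training
#' partition and evaluated on the held-out group, so no fold's test rows
#' influence any fitted component.
#'
#' @param windows peptide-window data frame.
#' @param config a [suc_config()].
#' @param folds number of folds.
#' @param seed seed for fold assignment and all fitted components.
#' @param methods encoder subset (defaults to all five).
#' @return object of class `cv_report`: `per_fold` data frame of
#'   `(Sn, Sp, Acc, MCC, F1, AUC)`, their `mean` and `std`, plus `folds`
#'   and `seed`.
#' @export
cross_validate <- function(windows, config = suc_config(), folds = 10,
                           seed = 1, methods = names(BLOCK_WIDTHS)) {
  y <- window_labels(windows)
  if (min(table(y)) < folds)
    stop("each class needs at least ", folds, " members")
  assignment <- stratified_folds(y, folds, derive_seed(seed, "cv_folds"))

  global_selector <- NULL
  if (isTRUE(config$global_lasso)) {
    # protocol of the original study: the selector sees the whole dataset
    # once, before cross-validation (leaks test information; off by default)
    model_all <- suc_train(windows, config = config, seed = seed,
                            methods = methods, fit_stack = FALSE)
    global_selector <- fit_lasso(model_all$X, y,
                                 lambda = config$stack$lasso_lambda,
                                 seed = derive_seed(seed, "lasso_global"),
                                 min_features = 1)
  }

  rows <- lapply(seq_len(folds), function(f) {
    tr <- windows[assignment != f, , drop = FALSE]
    te <- windows[assignment == f, , drop = FALSE]
    model <- suc_train(tr, config = config,
                        seed = derive_seed(seed, paste0("cvfold", f)),
                        methods = methods, selector = global_selector)
    prob <- suc_predict(model, te)$probability
    y_te <- window_labels(te)
    cm <- confusion_counts(prob, y_te)
    c(compute_metrics(cm[["TP"]], cm[["TN"]], cm[["FP"]], cm[["FN"]]),
      AUC = roc_auc(prob, y_te)$auc)
  })
  per_fold <- as.data.frame(do.call(rbind, rows))
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold),
                 std = apply(per_fold, 2, sd),
                 folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$folds, "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  print(round(rbind(mean = x$mean, std = x$std), 4))
  invisible(x)
}

#' Per-encoder ablation table
#'
#' Runs [cross_validate()] once per single-encoder feature set and once
#' for the fused 811-dimensional set, reporting mean and standard
#' deviation of each metric per row (five encoders plus `ALL`).
#'
#' @inheritParams cross_validate
#' @return list with `table` (one row per feature set) and `reports` (the
#'   underlying `cv_report` objects).
#' @export
ablation_encoders <- function(windows, config = suc_config(), folds = 10,
                              seed = 1) {
  sets <- c(as.list(names(BLOCK_WIDTHS)), list(names(BLOCK_WIDTHS)))
  names(sets) <- c(names(BLOCK_WIDTHS), "ALL")
  reports <- lapply(sets, function(m)
    cross_validate(windows, config = config, folds = folds, seed = seed,
                   methods = m))
  table <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(method = nm,
               width = sum(BLOCK_WIDTHS[sets[[nm]]]),
               t(r$mean), check.names = FALSE)
  }))
  list(table = table, reports = reports)
}

#' Signal-recovery experiment on synthetic peptide windows
#'
#' For each seed: generates a labeled synthetic dataset with a planted
#' compositional signal, holds out a stratified fraction, trains the full
#' pipeline on the remainder, and measures held-out AUC/Acc/MCC of the
#' stacked model and the held-out AUC of each refitted base learner.
#'
#' @param n_pos,n_neg class sizes of the generated dataset.
#' @param effect enrichment strength in `[0, 1]` (0 = null data).
#' @param seeds integer vector of seeds; one experiment per seed.
#' @param holdout held-out fraction per class.
#' @param config a [suc_config()].
#' @return data frame with one row per seed: `auc`, `acc`, `mcc` of the
#'   stack and `auc_svm`, `auc_bls`, `auc_gbdt` of the base learners.
#' @export
signal_recovery_experiment <- function(n_pos = 500, n_neg = 500,
                                       effect = 0.5, seeds = 1:10,
                                       holdout = 0.2,
                                       config = suc_config()) {
  rows <- lapply(seeds, function(sd) {
    windows <- generate_fixture(n_pos, n_neg, effect = effect, seed = sd)
    y <- window_labels(windows)
    te <- with_seed(derive_seed(sd, "holdout"), {
      sort(unlist(lapply(split(seq_along(y), y), function(ix)
        sample(ix, round(length(ix) * holdout)))))
    })
    model <- suc_train(windows[-te, , drop = FALSE], config = config,
                        seed = sd)
    te_windows <- windows[te, , drop = FALSE]
    prob <- suc_predict(model, te_windows)$probability
    y_te <- y[te]
    cm <- confusion_counts(prob, y_te)
    m <- compute_metrics(cm[["TP"]], cm[["TN"]], cm[["FP"]], cm[["FN"]])
    X_te <- encode_windows(te_windows, cbow_model = model$cbow,
                           methods = model$methods,
                           cgr_frequency_normalize =
                             model$config$cgr_frequency_normalize)
    base <- score_base_learners(model$stacking$base_models,
                                lasso_transform(model$stacking$selector, X_te))
    data.frame(seed = sd,
               auc = roc_auc(prob, y_te)$auc,
               acc = m[["Acc"]], mcc = m[["MCC"]],
               auc_svm = roc_auc(base[, "svm"], y_te)$auc,
               auc_bls = roc_auc(base[, "bls"], y_te)$auc,
               auc_gbdt = roc_auc(base[, "gbdt"], y_te)$auc)
  })
  do.call(rbind, rows)
}
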
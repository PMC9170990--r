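test_that("confusion metrics match hand-evaluated formulas", {
  perfect <- compute_metrics(TP = 30, TN = 30, FP = 0, FN = 0)
  expect_equal(unname(perfect), rep(1, 5))
  balanced <- compute_metrics(TP = 25, TN = 25, FP = 25, FN = 25)
  expect_equal(balanced[["Sn"]], 0.5)
  expect_equal(balanced[["Sp"]], 0.5)
  expect_equal(balanced[["Acc"]], 0.5)
  expect_equal(balanced[["MCC"]], 0)
  expect_equal(balanced[["F1"]], 0.5)
  m <- compute_metrics(TP = 8, FN = 2, TN = 7, FP = 3)
  expect_equal(m[["Sn"]], 0.8)
  expect_equal(m[["Sp"]], 0.7)
  expect_equal(m[["Acc"]], 0.75)
  expect_equal(m[["MCC"]], 50 / sqrt(11 * 10 * 10 * 9))
  expect_equal(m[["F1"]], 16 / 21)
  # degenerate denominators fall back to zero
  expect_equal(compute_metrics(0, 10, 0, 0)[["MCC"]], 0)
  expect_equal(compute_metrics(0, 10, 0, 0)[["F1"]], 0)
  expect_error(compute_metrics(-1, 2, 3, 4), "nonnegative")
})

test_that("accuracy decomposes into class-weighted Sn and Sp", {
  set.seed(10)
  for (i in 1:25) {
    cm <- sample(0:30, 4, replace = TRUE)
    if (cm[1] + cm[4] == 0 || cm[2] + cm[3] == 0) next
    m <- compute_metrics(cm[1], cm[2], cm[3], cm[4])
    P <- cm[1] + cm[4]
    N <- cm[2] + cm[3]
    expect_equal(m[["Acc"]], (m[["Sn"]] * P + m[["Sp"]] * N) / (P + N))
    expect_true(m[["MCC"]] >= -1 && m[["MCC"]] <= 1)
    expect_equal(m, oracle_metrics(cm[1], cm[2], cm[3], cm[4]))
  }
})

test_that("rank-based AUC equals exhaustive pairwise concordance", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), rep(c(0, 1), 3))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(20)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 1)  # coarse grid forces ties
    got <- roc_auc(scores, labels)$auc
    expect_equal(got, oracle_auc_pairs(scores, labels))
    # AUC of negated scores is the complement
    expect_equal(roc_auc(-scores, labels)$auc, 1 - got)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- runif(60)
  labels <- rbinom(60, 1, plogis(3 * (scores - 0.5)))
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))))
})

test_that("cross-validation partitions the data and reports per fold", {
  fx <- generate_fixture(20, 20, effect = 0.8, seed = 4)
  y <- sucstack:::window_labels(fx)
  folds <- sucstack:::stratified_folds(y, 4, seed = 1)
  expect_equal(sort(unique(folds)), 1:4)
  expect_equal(length(folds), 40)
  for (f in 1:4) expect_equal(sum(folds == f), 10)
  expect_true(all(table(folds, y) == 5))  # stratification
  expect_error(sucstack:::stratified_folds(y, 30, seed = 1), "at least")

  report <- cross_validate(fx, config = small_suc_config(), folds = 2,
                           seed = 1)
  expect_s3_class(report, "cv_report")
  expect_equal(nrow(report$per_fold), 2)
  expect_equal(unname(report$mean), unname(colMeans(report$per_fold)),
               tolerance = 1e-12)
  expect_equal(unname(report$std),
               unname(apply(report$per_fold, 2, sd)), tolerance = 1e-12)
  expect_output(print(report), "cross-validation")
})

test_that("ablation covers the five encoders plus the fused set", {
  fx <- generate_fixture(20, 20, effect = 0.9, seed = 6)
  ab <- ablation_encoders(fx, config = small_suc_config(), folds = 2,
                          seed = 1)
  expect_equal(nrow(ab$table), 6)
  expect_equal(ab$table$method,
               c("EBGW", "OneHot", "CBOW", "CGR", "AAF_DWT", "ALL"))
  expect_equal(ab$table$width[ab$table$method == "ALL"], 811)
  expect_equal(ab$table$width[ab$table$method == "EBGW"], 15)
})

test_that("positional one-hot features beat chaos-game counts on motif data", {
  # purely positional signal: both classes share the same overall flank
  # composition, but the enriched residues sit on opposite sides of K, so
  # position-aware one-hot can separate the classes while the
  # order-insensitive chaos-game occupancy summary has almost nothing to
  # work with
  positional_fixture <- function(n_per_class, effect, seed) {
    set.seed(seed)
    flank <- function(enriched) {
      res <- sample(sucstack:::AA_ALPHABET, 10, replace = TRUE)
      hit <- runif(10) < effect
      res[hit] <- sample(enriched, sum(hit), replace = TRUE)
      paste(res, collapse = "")
    }
    make <- function(n, up_set, down_set, tag) {
      vapply(seq_len(n), function(i)
        paste0(flank(up_set), "K", flank(down_set)), character(1))
    }
    data.frame(
      protein_id = sprintf("w%d", seq_len(2 * n_per_class)),
      position = 11L,
      label = factor(rep(c("positive", "negative"), each = n_per_class),
                     levels = c("negative", "positive")),
      residues = c(make(n_per_class, c("K", "G", "A"), "S"),
                   make(n_per_class, "S", c("K", "G", "A"))),
      stringsAsFactors = FALSE
    )
  }
  aucs <- sapply(1:10, function(s) {
    fx <- positional_fixture(20, effect = 0.6, seed = s)
    onehot <- cross_validate(fx, config = small_suc_config(), folds = 2,
                             seed = s, methods = "OneHot")
    cgr <- cross_validate(fx, config = small_suc_config(), folds = 2,
                          seed = s, methods = "CGR")
    c(onehot$mean[["AUC"]], cgr$mean[["AUC"]])
  })
  expect_gt(mean(aucs[1, ]), mean(aucs[2, ]))
})
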
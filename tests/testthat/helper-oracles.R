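# Independent oracles, coded from definitions and kept separate from the
# package's implementation paths.

# two-tap Haar analysis filter bank: convolve with the low/high filters
# and downsample by two, recursing on the low branch; odd-length inputs
# are extended by repeating the final sample (half-sample symmetric).
# Returns subbands [approximation L, detail L, ..., detail 1].
oracle_haar_filterbank <- function(x, levels = 3) {
  lo <- c(1, 1) / sqrt(2)
  hi <- c(1, -1) / sqrt(2)
  details <- list()
  a <- x
  for (l in seq_len(levels)) {
    if (length(a) %% 2L == 1L) a <- c(a, a[length(a)])
    conv <- function(f) {
      full <- as.numeric(stats::filter(c(a, 0), rev(f), sides = 1))[-1L]
      full[seq(1L, length(a), by = 2L)]   # downsample by 2
    }
    details[[l]] <- conv(hi)
    a <- conv(lo)
  }
  c(list(a), rev(details))
}

# AUC by exhaustive pairwise concordance (ties count one half)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}

# closed-form ridge regression on a design matrix (normal equations)
oracle_ridge <- function(A, y, c) {
  solve(t(A) %*% A + c * diag(ncol(A)), t(A) %*% y)
}

# hand evaluation of the five confusion-matrix metrics
oracle_metrics <- function(TP, TN, FP, FN) {
  den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  c(Sn = TP / (TP + FN), Sp = TN / (TN + FP),
    Acc = (TP + TN) / (TP + TN + FP + FN),
    MCC = if (den == 0) 0 else (TP * TN - FP * FN) / den,
    F1 = 2 * TP / (2 * TP + FP + FN))
}

# cheap ensemble settings for unit tests of mechanisms (not of the tuned
# study configuration)
small_stack_config <- function(...) {
  stack_config(gbdt = list(learning_rate = 0.27, max_depth = 6,
                           num_leaves = 15, n_estimators = 40),
               bls = list(n_windows = 10, n_enhance = 10),
               oof_folds = 3, ...)
}

small_suc_config <- function(...) {
  suc_config(cbow = list(d = 10, window = 5, epochs = 5, negative = 5),
              stack = small_stack_config(), ...)
}
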
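#' Fit an L1-penalized (LASSO) feature selector
#'
#' Minimizes `sum_i (y_i - w' x_i)^2 + lambda * ||w||_1` by coordinate
#' descent (via glmnet), treating the binary labels as a 0/1 regression
#' response. Columns are standardized to zero mean and unit variance
#' internally; coefficients are reported on the standardized scale.
#' Features with nonzero coefficients form the selected subset.
#'
#' @param X numeric feature matrix (n x p).
#' @param y binary labels in `{0, 1}` (or a factor coercible to them).
#' @param lambda nonnegative penalty on the sum-of-squares scale above, or
#'   `"cv"` to pick it by 5-fold cross-validated squared error over
#'   glmnet's logarithmic grid.
#' @param nfolds folds for `lambda = "cv"`.
#' @param seed seed controlling the cross-validation fold assignment.
#' @param min_features if the chosen penalty retains fewer than this many
#'   features (as happens under `lambda = "cv"` on signal-free data, where
#'   the intercept-only model wins), the penalty is relaxed to the largest
#'   value on the regularization path admitting at least `min_features`
#'   nonzero coefficients. Default 0 (no floor).
#' @return object of class `lasso_selector` with elements `lambda`,
#'   `coefficients` (length p, standardized scale) and `selected_indices`
#'   (sorted, 1-based).
#' @export
fit_lasso <- function(X, y, lambda = "cv", nfolds = 5, seed = 1,
                      min_features = 0) {
  X <- as.matrix(X)
  y <- if (is.factor(y)) as.integer(y == levels(y)[2L]) else as.numeric(y)
  if (!all(is.finite(X))) stop("X contains non-finite values")
  if (nrow(X) < 2) stop("need at least two samples")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  n <- nrow(X)
  if (identical(lambda, "cv")) {
    foldid <- with_seed(derive_seed(seed, "lasso_cv"), {
      unsplit(lapply(split(seq_len(n), y), function(ix)
        sample(rep_len(seq_len(nfolds), length(ix)))), y)
    })
    cvfit <- glmnet::cv.glmnet(Xs, y, family = "gaussian", alpha = 1,
                               foldid = foldid, standardize = FALSE)
    lam_glmnet <- cvfit$lambda.min
    lambda <- lam_glmnet * 2 * n   # report on the sum-of-squares scale
    fit <- cvfit$glmnet.fit
  } else {
    if (lambda < 0) stop("lambda must be nonnegative")
    lam_glmnet <- lambda / (2 * n) # glmnet scales the loss by 1/(2n)
    fit <- glmnet::glmnet(Xs, y, family = "gaussian", alpha = 1,
                          standardize = FALSE, thresh = 1e-12)
  }
  w <- as.numeric(coef(fit, s = lam_glmnet, exact = TRUE, x = Xs, y = y))[-1L]
  if (sum(w != 0) < min_features) {
    df_path <- fit$df
    ok <- which(df_path >= min_features)
    if (length(ok) == 0L)
      stop("no penalty on the path retains ", min_features, " feature(s)")
    lam_glmnet <- fit$lambda[ok[1L]]
    lambda <- lam_glmnet * 2 * n
    w <- as.numeric(coef(fit, s = lam_glmnet, exact = TRUE,
                         x = Xs, y = y))[-1L]
  }
  structure(list(
    lambda = lambda,
    lambda_glmnet = lam_glmnet,
    coefficients = w,
    selected_indices = which(w != 0),
    p = ncol(X),
    fitted_on = c(n = n, p = ncol(X), checksum = sum(X) + sum(y))
  ), class = "lasso_selector")
}

#' Persist or restore a fitted selector as JSON
#'
#' The JSON object carries the penalty, the coefficient vector and the
#' selected indices, so a selection can be archived or shared without R
#' serialization.
#'
#' @param selector fitted [fit_lasso()] object.
#' @param path output (or input) JSON file path.
#' @return `write_selector` returns `path` invisibly; `read_selector`
#'   returns the restored `lasso_selector`.
#' @export
write_selector <- function(selector, path) {
  stopifnot(inherits(selector, "lasso_selector"))
  jsonlite::write_json(
    list(lambda = selector$lambda,
         lambda_glmnet = selector$lambda_glmnet,
         coefficients = selector$coefficients,
         selected_indices = selector$selected_indices,
         p = selector$p),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selector
#' @export
read_selector <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(lambda = x$lambda, lambda_glmnet = x$lambda_glmnet,
                 coefficients = as.numeric(x$coefficients),
                 selected_indices = as.integer(x$selected_indices),
                 p = as.integer(x$p)),
            class = "lasso_selector")
}

#' Reduce a feature matrix to the LASSO-selected columns
#'
#' @param selector fitted [fit_lasso()] object.
#' @param X numeric matrix with the same number of columns the selector
#'   was fitted on.
#' @return matrix of the selected columns, in selected-index order.
#' @export
lasso_transform <- function(selector, X) {
  stopifnot(inherits(selector, "lasso_selector"))
  X <- as.matrix(X)
  if (ncol(X) != selector$p)
    stop("X has ", ncol(X), " columns; selector was fitted on ", selector$p)
  if (length(selector$selected_indices) == 0L)
    stop("selector retained no features; refit with a smaller lambda")
  X[, selector$selected_indices, drop = FALSE]
}
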
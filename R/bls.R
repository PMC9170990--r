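#' Broad learning system configuration
#'
#' Defaults are the tuned values used throughout the package: 3 feature
#' nodes per mapping window, 100 mapping windows, 100 enhancement nodes,
#' enhancement shrinkage 0.9 and ridge regularization 2^-30.
#'
#' @param n_feature feature nodes per mapping window (N1).
#' @param n_windows number of mapping windows (N2).
#' @param n_enhance number of enhancement nodes (N3); 0 disables the
#'   enhancement layer.
#' @param s enhancement shrinkage scale; activations lie in `[-s, s]`.
#' @param c ridge regularization of the output solve.
#' @param activation enhancement nonlinearity.
#' @return list of class `bls_config`.
#' @export
bls_config <- function(n_feature = 3, n_windows = 100, n_enhance = 100,
                       s = 0.9, c = 2^-30,
                       activation = c("tanh", "identity")) {
  structure(list(n_feature = as.integer(n_feature),
                 n_windows = as.integer(n_windows),
                 n_enhance = as.integer(n_enhance),
                 s = s, c = c,
                 activation = match.arg(activation)),
            class = "bls_config")
}

# random matrix with orthonormal columns (extra columns beyond the row
# count are unit-normalized random directions)
rand_orthonormal <- function(nr, nc) {
  M <- matrix(rnorm(nr * nc), nr, nc)
  k <- min(nr, nc)
  Q <- qr.Q(qr(M))[, seq_len(k), drop = FALSE]
  if (nc > k) {
    extra <- matrix(rnorm(nr * (nc - k)), nr)
    extra <- sweep(extra, 2, sqrt(colSums(extra^2)), "/")
    Q <- cbind(Q, extra)
  }
  Q
}

#' Fit a broad learning system classifier
#'
#' One-shot broad learning: per mapping window, random linear features
#' `Z_i = [X 1] We_i` (weights uniform on `[-1, 1]`) are min-max rescaled
#' to `[0, 1]`; the concatenated mapped features feed a random orthonormal
#' enhancement layer `H = act(s * [Z 1] Wh / r_max)` whose pre-activations
#' are shrunk so activations lie within `[-s, s]`; the output weights over
#' `A = [Z H]` are solved as a ridge system
#' `(A'A + cI)^-1 A'y`. Deterministic given the seed.
#'
#' @param X numeric feature matrix (n x d).
#' @param y binary labels in `{0, 1}`.
#' @param config a [bls_config()].
#' @param seed RNG seed for the random weights.
#' @return object of class `bls_model`.
#' @export
bls_fit <- function(X, y, config = bls_config(), seed = 1) {
  X <- as.matrix(X)
  y <- if (is.factor(y)) as.integer(y == levels(y)[2L]) else as.numeric(y)
  if (nrow(X) < 2) stop("need at least two samples")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (all(apply(X, 2, sd) == 0)) stop("X is constant; nothing to learn")
  cfg <- config
  d <- ncol(X)
  with_seed(derive_seed(seed, "bls"), {
    Xb <- cbind(X, 1)
    We <- lapply(seq_len(cfg$n_windows), function(i)
      matrix(runif((d + 1L) * cfg$n_feature, -1, 1), d + 1L, cfg$n_feature))
    zmin <- zmax <- vector("list", cfg$n_windows)
    Z <- matrix(0, nrow(X), cfg$n_feature * cfg$n_windows)
    for (i in seq_len(cfg$n_windows)) {
      Zi <- Xb %*% We[[i]]
      zmin[[i]] <- apply(Zi, 2, min)
      rng <- apply(Zi, 2, max) - zmin[[i]]
      rng[rng == 0] <- 1
      zmax[[i]] <- zmin[[i]] + rng
      cols <- ((i - 1L) * cfg$n_feature + 1L):(i * cfg$n_feature)
      Z[, cols] <- sweep(sweep(Zi, 2, zmin[[i]]), 2, rng, "/")
    }
    if (cfg$n_enhance > 0L) {
      Wh <- rand_orthonormal(ncol(Z) + 1L, cfg$n_enhance)
      pre <- cbind(Z, 1) %*% Wh
      r_max <- max(abs(pre))
      if (r_max == 0) r_max <- 1
      act <- if (cfg$activation == "tanh") tanh else identity
      H <- act(cfg$s * pre / r_max)
    } else {
      Wh <- NULL
      r_max <- 1
      H <- matrix(0, nrow(X), 0L)
    }
    A <- cbind(Z, H)
    # tol = 0: with very small c the ridge system is near-singular by
    # design (interpolation regime); LAPACK still yields a usable solution
    Wout <- solve(crossprod(A) + cfg$c * diag(ncol(A)), crossprod(A, y),
                  tol = 0)
    structure(list(config = cfg, d = d, We = We, zmin = zmin, zmax = zmax,
                   Wh = Wh, r_max = r_max, Wout = Wout, seed = seed),
              class = "bls_model")
  })
}

# mapped + enhancement design matrix for new data, using stored scalings
bls_design <- function(model, X) {
  cfg <- model$config
  Xb <- cbind(X, 1)
  Z <- matrix(0, nrow(X), cfg$n_feature * cfg$n_windows)
  for (i in seq_len(cfg$n_windows)) {
    Zi <- Xb %*% model$We[[i]]
    rng <- model$zmax[[i]] - model$zmin[[i]]
    cols <- ((i - 1L) * cfg$n_feature + 1L):(i * cfg$n_feature)
    Z[, cols] <- sweep(sweep(Zi, 2, model$zmin[[i]]), 2, rng, "/")
  }
  if (cfg$n_enhance > 0L) {
    act <- if (cfg$activation == "tanh") tanh else identity
    H <- act(cfg$s * (cbind(Z, 1) %*% model$Wh) / model$r_max)
  } else {
    H <- matrix(0, nrow(X), 0L)
  }
  cbind(Z, H)
}

#' Score new samples with a fitted broad learning system
#'
#' The raw ridge output `A Wout` is clipped to `[0, 1]` to serve as a
#' probability-like score; the mapping is monotone in the raw output.
#'
#' @param model fitted [bls_fit()] object.
#' @param X numeric matrix with the training dimensionality.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
bls_score <- function(model, X) {
  stopifnot(inherits(model, "bls_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop("X has ", ncol(X), " columns; model was fitted on ", model$d)
  raw <- as.numeric(bls_design(model, X) %*% model$Wout)
  pmin(pmax(raw, 0), 1)
}
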
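#' Pipeline configuration
#'
#' Bundles every tunable of the prediction pipeline with the tuned
#' defaults: CBOW embedding training settings, the chaos-game count
#' normalization flag, the selection protocol flag, and the stacking
#' ensemble configuration.
#'
#' @param cbow list of [cbow_train()] arguments (`d`, `window`, `epochs`,
#'   `negative`).
#' @param cgr_frequency_normalize passed to [cgr_encode()].
#' @param global_lasso if `TRUE`, [cross_validate()] fits the
#'   LASSO selector once on the whole dataset before splitting (the
#'   original protocol, which leaks test information into selection);
#'   default `FALSE` refits the selector inside every training fold.
#' @param r window flank radius.
#' @param stack a [stack_config()].
#' @return list of class `suc_config`.
#' @export
suc_config <- function(cbow = list(d = 100, window = 5, epochs = 50,
                                    negative = 5),
                        cgr_frequency_normalize = FALSE,
                        global_lasso = FALSE,
                        r = 10,
                        stack = stack_config()) {
  structure(list(cbow = cbow,
                 cgr_frequency_normalize = cgr_frequency_normalize,
                 global_lasso = global_lasso,
                 r = r, stack = stack),
            class = "suc_config")
}

#' Train the full succinylation prediction pipeline
#'
#' Trains the CBOW embeddings on the training windows (only), encodes the
#' windows into the fused feature matrix, and fits the stacking ensemble
#' (LASSO selection, out-of-fold base scores, logistic meta-learner).
#'
#' @param windows training peptide-window data frame.
#' @param config a [suc_config()].
#' @param seed seed fanned out deterministically to every stage.
#' @param methods encoder subset (defaults to all five).
#' @param selector optional pre-fitted selector (global-selection protocol).
#' @param fit_stack internal; if `FALSE`, stop after encoding and return
#'   the feature matrix in the `X` element.
#' @return object of class `suc_model`.
#' @export
suc_train <- function(windows, config = suc_config(), seed = 1,
                       methods = names(BLOCK_WIDTHS), selector = NULL,
                       fit_stack = TRUE) {
  cbow <- NULL
  if ("CBOW" %in% methods)
    cbow <- do.call(cbow_train,
                    c(list(windows = windows,
                           seed = derive_seed(seed, "cbow")),
                      config$cbow))
  X <- encode_windows(windows, cbow_model = cbow, methods = methods,
                      cgr_frequency_normalize = config$cgr_frequency_normalize)
  stacking <- NULL
  if (fit_stack)
    stacking <- stack_fit(X, window_labels(windows), config = config$stack,
                          seed = derive_seed(seed, "stack"),
                          selector = selector)
  structure(list(cbow = cbow, stacking = stacking, config = config,
                 methods = methods, seed = seed,
                 X = if (fit_stack) NULL else X),
            class = "suc_model")
}

#' Predict succinylation probabilities for peptide windows
#'
#' @param model fitted [suc_train()] object.
#' @param windows peptide-window data frame to score.
#' @param threshold positive-call probability threshold.
#' @return data frame `protein_id`, `position`, `probability`, `call`
#'   (factor `negative`/`positive`).
#' @export
suc_predict <- function(model, windows, threshold = 0.5) {
  stopifnot(inherits(model, "suc_model"))
  X <- encode_windows(windows, cbow_model = model$cbow,
                      methods = model$methods,
                      cgr_frequency_normalize =
                        model$config$cgr_frequency_normalize)
  prob <- stack_predict(model$stacking, X)
  data.frame(protein_id = windows$protein_id,
             position = windows$position,
             probability = prob,
             call = factor(ifelse(prob >= threshold, "positive", "negative"),
                           levels = c("negative", "positive")),
             stringsAsFactors = FALSE)
}
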
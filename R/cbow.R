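# overlapping k-mers of a window; words containing 'X' are never formed
window_tokens <- function(residues, l) {
  n <- nchar(residues)
  if (n < l) return(character(0))
  toks <- substring(residues, seq_len(n - l + 1L), seq_len(n - l + 1L) + l - 1L)
  toks[!grepl("X", toks, fixed = TRUE)]
}

#' Train CBOW k-mer embeddings on a window corpus
#'
#' Each window is split into overlapping words of length 2 (20 words per
#' 21-mer) and, separately, of length 3 (19 words). One CBOW (word2vec)
#' embedding model with negative sampling is trained per word length; the
#' vocabularies are the deduplicated word sets of the corpus. Training is
#' deterministic given the seed.
#'
#' @param windows data frame of peptide windows, or a character vector of
#'   residue strings.
#' @param d embedding dimension.
#' @param seed RNG seed for initialization and negative sampling.
#' @param window one-sided context width.
#' @param epochs training passes over the corpus.
#' @param negative negative samples per target word.
#' @param alpha initial learning rate.
#' @return object of class `cbow_model` holding, per word length, the
#'   vocabulary and the `v x d` embedding matrix.
#' @export
cbow_train <- function(windows, d = 100, seed = 1, window = 5, epochs = 50,
                       negative = 5, alpha = 0.025) {
  residues <- if (is.data.frame(windows)) windows$residues else windows
  if (length(residues) == 0L) stop("empty corpus")
  fit_one <- function(l) {
    sentences <- lapply(residues, window_tokens, l = l)
    sentences <- sentences[lengths(sentences) > 0L]
    if (length(sentences) == 0L) stop("no length-", l, " words in corpus")
    vocab <- sort(unique(unlist(sentences)))
    ids <- lapply(sentences, function(s) match(s, vocab))
    emb <- cbow_train_cpp(ids, length(vocab), as.integer(d),
                          as.integer(window), as.integer(epochs),
                          as.integer(negative), alpha,
                          derive_seed(seed, paste0("cbow", l)))
    rownames(emb) <- vocab
    list(vocab = vocab, embeddings = emb)
  }
  structure(list(wordbook_2 = fit_one(2L), wordbook_3 = fit_one(3L), d = d),
            class = "cbow_model")
}

#' Encode a peptide window with a fitted CBOW model
#'
#' The window's 2-mer word tokens are averaged in embedding space (100
#' dims by default) and concatenated with the average over its 3-mer
#' tokens. Out-of-vocabulary words contribute a zero vector while still
#' counting in the denominator; a window with no tokens yields zeros.
#'
#' @param residues window residue string.
#' @param model fitted [cbow_train()] model.
#' @return numeric vector of length `2 * d` (200 by default).
#' @export
cbow_encode <- function(residues, model) {
  stopifnot(inherits(model, "cbow_model"))
  mean_vec <- function(book, l) {
    toks <- window_tokens(residues, l)
    if (length(toks) == 0L) return(numeric(model$d))
    hit <- match(toks, book$vocab)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) return(numeric(model$d))
    colSums(book$embeddings[hit, , drop = FALSE]) / length(toks)
  }
  out <- c(mean_vec(model$wordbook_2, 2L), mean_vec(model$wordbook_3, 3L))
  if (length(out) == BLOCK_WIDTHS[["CBOW"]]) feature_block("CBOW", out) else out
}
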
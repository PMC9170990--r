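# Residue groups for the grouping-weight encoder: neutral/non-polar,
# neutral/polar, acidic, basic.
EBGW_GROUPS <- list(
  G1 = c("A", "F", "G", "I", "L", "M", "P", "V", "W"),
  G2 = c("C", "N", "Q", "S", "T", "Y"),
  G3 = c("D", "E"),
  G4 = c("H", "K", "R")
)

# one representative codon per amino acid for reverse translation
CODON_TABLE <- c(
  A = "GCT", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGT",
  H = "CAC", I = "ATT", K = "AAG", L = "CTA", M = "ATG", N = "AAC",
  P = "CCA", Q = "CAG", R = "CGA", S = "TCA", T = "ACT", V = "GTG",
  W = "TGG", Y = "TAC"
)

BLOCK_WIDTHS <- c(EBGW = 15L, OneHot = 420L, CBOW = 200L, CGR = 16L,
                  AAF_DWT = 160L)

window_chars <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, c(AA_ALPHABET, "X"))
  if (length(bad))
    stop("residues outside the amino-acid alphabet plus 'X': ",
         paste(bad, collapse = ", "))
  chars
}

feature_block <- function(name, values) {
  stopifnot(name %in% names(BLOCK_WIDTHS),
            length(values) == BLOCK_WIDTHS[[name]])
  structure(as.numeric(values), block = name)
}

#' Grouping-weight (EBGW) encoding of a peptide window
#'
#' The window is mapped to three binary sequences by membership in unions
#' of four physicochemical residue groups (neutral/non-polar,
#' neutral/polar, acidic, basic); each binary sequence is summarized by
#' the running frequency of ones `f(n) = w(n)/n` sampled at
#' `n = Q, 2Q, ..., K_points * Q` with `Q = floor(L / K_points)`.
#' Non-standard residues (`'X'`) belong to no group.
#'
#' @param residues window residue string (length 21 by default usage).
#' @param K_points number of sampling points per binary sequence.
#' @return numeric vector of length `3 * K_points` with values in `[0, 1]`,
#'   ordered S1, S2, S3.
#' @export
ebgw_encode <- function(residues, K_points = 5) {
  chars <- window_chars(residues)
  L <- length(chars)
  if (K_points < 1 || L %/% K_points < 1)
    stop("K_points must satisfy floor(L / K_points) >= 1")
  Q <- L %/% K_points
  at <- Q * seq_len(K_points)
  g <- EBGW_GROUPS
  sample_freq <- function(members) {
    s <- as.integer(chars %in% members)
    (cumsum(s) / seq_along(s))[at]
  }
  feature_block("EBGW", c(
    sample_freq(c(g$G1, g$G2)),
    sample_freq(c(g$G1, g$G3)),
    sample_freq(c(g$G1, g$G4))
  ))
}

#' One-hot encoding of a peptide window
#'
#' Each position is a 20-bit indicator over the alphabet
#' `ACDEFGHIKLMNPQRSTVWY`; positions are concatenated N- to C-terminus.
#' `'X'` yields an all-zero block.
#'
#' @param residues window residue string.
#' @return numeric 0/1 vector of length `20 * nchar(residues)` (420 for a
#'   21-residue window).
#' @export
onehot_encode <- function(residues) {
  chars <- window_chars(residues)
  out <- matrix(0, nrow = 20L, ncol = length(chars))
  hit <- match(chars, AA_ALPHABET)
  keep <- !is.na(hit)
  out[cbind(hit[keep], which(keep))] <- 1
  feature_block("OneHot", as.numeric(out))
}

#' Reverse-translate a peptide to a nucleotide sequence
#'
#' Each standard residue is replaced by its fixed representative codon;
#' `'X'` contributes no codon.
#'
#' @param residues window residue string.
#' @return nucleotide string of length `3 *` (number of standard residues).
#' @export
reverse_translate <- function(residues) {
  chars <- window_chars(residues)
  paste(CODON_TABLE[chars[chars != "X"]], collapse = "")
}

#' Chaos-game representation encoding of a peptide window
#'
#' The window is reverse-translated to nucleotides and the chaos-game
#' iteration `CGR_i = theta * (CGR_{i-1} + g_i)` is run from
#' `CGR_0 = (0.5, 0.5)` with corner coefficients A = (0,0), C = (0,1),
#' G = (1,0), T = (1,1). The unit square is divided into a `grid x grid`
#' lattice of equal half-open cells (upper edges closed on the last
#' row/column); the per-cell point counts are passed through the logistic
#' `1 / (1 + exp(-count))`.
#'
#' @param residues window residue string.
#' @param theta contraction factor of the iteration.
#' @param grid cells per side (16 features for the default 4).
#' @param frequency_normalize divide counts by the number of points before
#'   the logistic (default `FALSE`: the logistic is applied to raw counts,
#'   so cells holding four or more points saturate near 1).
#' @return numeric vector of length `grid^2`, row-major over cells.
#' @export
cgr_encode <- function(residues, theta = 0.5, grid = 4,
                       frequency_normalize = FALSE) {
  nuc <- reverse_translate(residues)
  counts <- numeric(grid * grid)
  n <- nchar(nuc)
  if (n > 0) {
    corners <- list(A = c(0, 0), C = c(0, 1), G = c(1, 0), T = c(1, 1))
    pt <- c(0.5, 0.5)
    for (ch in strsplit(nuc, "", fixed = TRUE)[[1L]]) {
      pt <- theta * (pt + corners[[ch]])
      cx <- min(floor(grid * pt[1L]), grid - 1L)
      cy <- min(floor(grid * pt[2L]), grid - 1L)
      idx <- cy * grid + cx + 1L
      counts[idx] <- counts[idx] + 1
    }
    if (frequency_normalize) counts <- counts / n
  }
  feature_block("CGR", plogis(counts))
}

# level-`levels` Haar pyramid with half-sample symmetric extension at the
# right edge for odd lengths; returns subbands ordered
# [approximation L, detail L, ..., detail 1]
haar_dwt <- function(x, levels = 3) {
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    if (length(a) %% 2L == 1L) a <- c(a, a[length(a)])
    odd <- a[seq(1L, length(a), by = 2L)]
    even <- a[seq(2L, length(a), by = 2L)]
    details[[l]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  c(list(a), rev(details))
}

#' Wavelet summary of physicochemical profiles (AAF_DWT encoding)
#'
#' For each of the ten physicochemical properties, the window is mapped to
#' a numeric series of standardized property values (`'X'` contributes 0),
#' decomposed by a level-3 Haar wavelet transform into four subbands
#' (approximation level 3, then details 3, 2, 1), and each subband is
#' summarized by its maximum, minimum, mean, and population standard
#' deviation. Per property the 16 statistics are ordered as the four
#' maxima, four minima, four means, four standard deviations; the ten
#' property vectors are concatenated.
#'
#' @param residues window residue string.
#' @param table standardized property table (see [property_table()]).
#' @param levels decomposition depth.
#' @return numeric vector of length `16 *` (number of properties); 160 for
#'   the default table.
#' @export
aaf_dwt_encode <- function(residues, table = property_table(), levels = 3) {
  if (!is_standardized(table))
    stop("property table is not standardized; see standardize_properties()")
  chars <- window_chars(residues)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- lapply(seq_len(ncol(table)), function(p) {
    vals <- ifelse(chars == "X", 0, table[chars, p])
    bands <- haar_dwt(as.numeric(vals), levels = levels)
    c(vapply(bands, max, numeric(1)),
      vapply(bands, min, numeric(1)),
      vapply(bands, mean, numeric(1)),
      vapply(bands, pop_sd, numeric(1)))
  })
  feature_block("AAF_DWT", unlist(out))
}

#' Fuse the five encoder blocks into one feature vector
#'
#' @param blocks named list with exactly the elements `EBGW`, `OneHot`,
#'   `CBOW`, `CGR`, `AAF_DWT` of widths 15, 420, 200, 16, 160.
#' @return numeric vector of length 811 with a `layout` attribute (data
#'   frame of block name, 0-based offset, width) recording the fixed
#'   concatenation order.
#' @export
fuse <- function(blocks) {
  wanted <- names(BLOCK_WIDTHS)
  if (!setequal(names(blocks), wanted) || anyDuplicated(names(blocks)))
    stop("need exactly one block of each of: ", paste(wanted, collapse = ", "))
  blocks <- blocks[wanted]
  widths <- vapply(blocks, length, integer(1))
  if (!all(widths == BLOCK_WIDTHS))
    stop("block width mismatch: got ", paste(widths, collapse = "/"),
         ", expected ", paste(BLOCK_WIDTHS, collapse = "/"))
  out <- unlist(blocks, use.names = FALSE)
  attr(out, "layout") <- data.frame(
    block = wanted,
    offset = cumsum(c(0L, unname(widths)))[seq_along(wanted)],
    width = unname(widths)
  )
  out
}

#' Encode peptide windows into the fused feature matrix
#'
#' Applies the requested encoders to every window and concatenates the
#' blocks in the fixed order EBGW, OneHot, CBOW, CGR, AAF_DWT. The CBOW
#' block requires a fitted [cbow_train()] model.
#'
#' @param windows data frame from [build_dataset()] or
#'   [generate_fixture()].
#' @param cbow_model fitted CBOW embedding model (needed only when
#'   `"CBOW"` is among `methods`).
#' @param methods subset of encoders to apply, in canonical order.
#' @param table standardized property table for the wavelet encoder.
#' @param cgr_frequency_normalize passed to [cgr_encode()].
#' @return numeric matrix with one row per window; 811 columns for the
#'   full method set. Column names identify the owning block.
#' @export
encode_windows <- function(windows, cbow_model = NULL,
                           methods = names(BLOCK_WIDTHS),
                           table = property_table(),
                           cgr_frequency_normalize = FALSE) {
  methods <- match.arg(methods, names(BLOCK_WIDTHS), several.ok = TRUE)
  methods <- names(BLOCK_WIDTHS)[names(BLOCK_WIDTHS) %in% methods]
  if ("CBOW" %in% methods && is.null(cbow_model))
    stop("a fitted CBOW model is required to compute the CBOW block")
  encode_one <- function(res) {
    parts <- list()
    if ("EBGW" %in% methods) parts$EBGW <- ebgw_encode(res)
    if ("OneHot" %in% methods) parts$OneHot <- onehot_encode(res)
    if ("CBOW" %in% methods) parts$CBOW <- cbow_encode(res, cbow_model)
    if ("CGR" %in% methods)
      parts$CGR <- cgr_encode(res, frequency_normalize = cgr_frequency_normalize)
    if ("AAF_DWT" %in% methods) parts$AAF_DWT <- aaf_dwt_encode(res, table = table)
    unlist(parts, use.names = FALSE)
  }
  widths <- BLOCK_WIDTHS[methods]
  if ("CBOW" %in% methods) widths[["CBOW"]] <- 2L * cbow_model$d
  X <- t(vapply(windows$residues, encode_one, numeric(sum(widths))))
  rownames(X) <- NULL
  colnames(X) <- unlist(lapply(methods, function(m)
    paste0(m, "_", seq_len(widths[[m]]))))
  X
}
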
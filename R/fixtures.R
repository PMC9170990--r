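#' Generate labeled synthetic peptide windows
#'
#' Produces K-centered windows whose flanking residues are drawn from a
#' mixture of the uniform background over the 20 amino acids and a
#' class-specific enriched residue set, with mixture weight `effect`.
#' The planted signal is purely positional-compositional: by default
#' lysine, glycine and alanine are over-represented around positives and
#' serine around negatives, mimicking the compositional differences
#' observed around real succinylation sites.
#'
#' @param n_pos,n_neg number of positive / negative windows.
#' @param effect enrichment strength in `[0, 1]`; 0 gives identically
#'   distributed classes (null data).
#' @param enriched_pos residues over-represented around positives.
#' @param enriched_neg residues over-represented around negatives.
#' @param seed RNG seed.
#' @param r flank radius (windows have `2r + 1` residues).
#' @return peptide-window data frame as from [build_dataset()].
#' @export
generate_fixture <- function(n_pos, n_neg, effect = 0.5,
                             enriched_pos = c("K", "G", "A"),
                             enriched_neg = "S",
                             seed = 1, r = 10) {
  stopifnot(n_pos >= 1, n_neg >= 1, effect >= 0, effect <= 1)
  with_seed(derive_seed(seed, "fixture"), {
    draw_flanks <- function(n, enriched) {
      flat <- sample(AA_ALPHABET, n * 2 * r, replace = TRUE)
      from_enriched <- runif(n * 2 * r) < effect
      flat[from_enriched] <- sample(enriched, sum(from_enriched),
                                    replace = TRUE)
      matrix(flat, nrow = n)
    }
    build <- function(n, enriched, tag) {
      flanks <- draw_flanks(n, enriched)
      vapply(seq_len(n), function(i)
        paste(c(flanks[i, seq_len(r)], "K", flanks[i, r + seq_len(r)]),
              collapse = ""), character(1))
    }
    data.frame(
      protein_id = c(sprintf("pos_%d", seq_len(n_pos)),
                     sprintf("neg_%d", seq_len(n_neg))),
      position = r + 1L,
      label = factor(rep(c("positive", "negative"), c(n_pos, n_neg)),
                     levels = c("negative", "positive")),
      residues = c(build(n_pos, enriched_pos, "pos"),
                   build(n_neg, enriched_neg, "neg")),
      stringsAsFactors = FALSE
    )
  })
}

#' Write synthetic windows as a FASTA plus annotation fixture
#'
#' Each window becomes one FASTA record (the window itself, so every site
#' is interior and needs no padding) and one TSV annotation row with
#' `position = r + 1`. Reading the pair back through [build_dataset()]
#' reproduces the window list exactly.
#'
#' @param windows peptide-window data frame.
#' @param dir output directory (created if missing).
#' @return named character vector with elements `fasta` and `annotations`.
#' @export
write_fixture <- function(windows, dir) {
  stopifnot(nrow(windows) >= 1)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir)
  fasta <- file.path(dir, "fixture.fasta")
  ann <- file.path(dir, "fixture_sites.tsv")
  writeLines(paste0(">", windows$protein_id, "\n", windows$residues), fasta)
  write.table(
    data.frame(protein_id = windows$protein_id,
               position = (nchar(windows$residues) + 1L) %/% 2L,
               label = as.integer(windows$label == "positive")),
    ann, sep = "\t", quote = FALSE, row.names = FALSE
  )
  c(fasta = fasta, annotations = ann)
}
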
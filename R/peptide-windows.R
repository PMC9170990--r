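#' Read a FASTA file of protein sequences
#'
#' Sequences are upper-cased and stop codons (`*`) are stripped; the id of
#' each record is the header token up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return named character vector mapping protein id to sequence. An empty
#'   file yields an empty vector.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "mka"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(setNames(character(0), character(0)))
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: line ", first, " is not a header ('>') line")
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- gsub("*", "", toupper(as.character(seqs)), fixed = TRUE)
  setNames(out, ids)
}

#' Extract a K-centered peptide window with mirror-image padding
#'
#' Returns the `2r + 1` residues centered on the lysine at `position`
#' (1-based). Where the protein is too short on one side, the deficit is
#' filled with the mirror image — the reversal of the corresponding
#' residues on the opposite side of K — so that the flank extends
#' palindromically around the center. If the opposite side is itself too
#' short to supply the mirror (pathologically short proteins), the
#' outermost remaining slots are filled with `'X'`.
#'
#' @param sequence protein sequence (single string).
#' @param position 1-based index of the central lysine.
#' @param r flank radius; the window has `2r + 1` residues.
#' @return character scalar of length `2r + 1` with `'K'` at the center
#'   (0-based center index `r`).
#' @export
#' @examples
#' extract_window("KACDE", 1, r = 2)     # "CAKAC"
#' extract_window("AAAAKAAAA", 5, r = 2) # "AAKAA"
extract_window <- function(sequence, position, r = 10) {
  n <- nchar(sequence)
  if (n < 1) stop("sequence must have at least one residue")
  if (r < 1) stop("r must be >= 1")
  if (position < 1 || position > n)
    stop("position ", position, " outside sequence of length ", n)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (chars[position] != "K")
    stop("residue at position ", position, " is '", chars[position],
         "', not 'K'")
  up <- if (position > 1) chars[max(1L, position - r):(position - 1L)] else character(0)
  down <- if (position < n) chars[(position + 1L):min(n, position + r)] else character(0)
  pad <- function(flank, opposite, side) {
    need <- r - length(flank)
    if (need <= 0L) return(flank)
    mirror <- rev(opposite[seq_len(min(need, length(opposite)))])
    fill <- rep("X", need - length(mirror))
    # mirrored residues sit adjacent to the existing flank; X fills outward
    if (side == "up") c(fill, mirror, flank) else c(flank, mirror, fill)
  }
  paste(c(pad(up, down, "up"), "K", pad(down, up, "down")), collapse = "")
}

#' Build a labeled peptide-window dataset from FASTA plus site annotations
#'
#' The annotation file is a TSV with a header and columns `protein_id`,
#' `position` (1-based index of the lysine) and `label` (1 = succinylated,
#' 0 = not). One window is produced per annotation, in annotation order.
#'
#' @param fasta path to the protein FASTA file.
#' @param annotations path to the TSV annotation file.
#' @param r flank radius (default 10, i.e. 21-residue windows).
#' @return data frame with columns `protein_id`, `position`, `label`
#'   (factor with levels `negative`, `positive`) and `residues` (the
#'   `2r + 1`-long window).
#' @export
build_dataset <- function(fasta, annotations, r = 10) {
  seqs <- read_fasta(fasta)
  ann <- read.delim(annotations, stringsAsFactors = FALSE)
  required <- c("protein_id", "position", "label")
  if (!all(required %in% names(ann)))
    stop("annotation file must have columns: ", paste(required, collapse = ", "))
  missing <- setdiff(unique(ann$protein_id), names(seqs))
  if (length(missing))
    stop("annotated proteins absent from FASTA: ", paste(missing, collapse = ", "))
  if (!all(ann$label %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  residue_at <- substr(seqs[ann$protein_id], ann$position, ann$position)
  bad <- which(residue_at != "K")
  if (length(bad))
    stop("annotations whose residue is not 'K' (rows): ",
         paste(bad, collapse = ", "))
  windows <- vapply(seq_len(nrow(ann)), function(i) {
    extract_window(seqs[[ann$protein_id[i]]], ann$position[i], r = r)
  }, character(1))
  data.frame(
    protein_id = ann$protein_id,
    position   = as.integer(ann$position),
    label      = factor(ifelse(ann$label == 1, "positive", "negative"),
                        levels = c("negative", "positive")),
    residues   = windows,
    stringsAsFactors = FALSE
  )
}

# numeric 0/1 response from the label factor
window_labels <- function(windows) as.integer(windows$label == "positive")
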
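# AAindex accessions for the ten physicochemical properties used by the
# wavelet encoder (values taken from the AAindex database bundled with
# seqinr).
PROPERTY_ACCESSIONS <- c(
  hydrophobicity_consensus   = "EISD840101", # consensus normalized hydrophobicity
  positive_charge            = "FAUJ880111",
  partition_energy           = "GUYH850101",
  net_charge                 = "KLEP840101",
  beta_strand_preference     = "LIFS790101", # all beta-strands
  beta_strand_antiparallel   = "LIFS790103",
  mean_polarity              = "RADA880108",
  z3_principal_property      = "WOLS870103",
  partition_energy_wertz     = "GUYH850102", # Wertz-Scheraga apparent partition energy
  ifh_scale_weight           = "JACR890101"
)

#' Amino-acid physicochemical property table
#'
#' Returns the 20 x 10 table of physicochemical property values used by
#' [aaf_dwt_encode()]: consensus normalized hydrophobicity, positive
#' charge, partition energy, net charge, conformational preferences for
#' all and for antiparallel beta-strands, mean polarity, the z3 principal
#' property, apparent partition energy from the Wertz-Scheraga index, and
#' IFH scale weights. Values come from the AAindex database (via seqinr).
#'
#' @param standardize if `TRUE` (default), each property column is
#'   standardized to zero mean and unit standard deviation over the 20
#'   amino acids; the transformation is idempotent.
#' @return numeric matrix, rows named by the one-letter amino-acid codes
#'   (alphabetical), columns by property.
#' @export
property_table <- function(standardize = TRUE) {
  key <- if (standardize) "std" else "raw"
  if (!is.null(.property_cache[[key]])) return(.property_cache[[key]])
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  tab <- sapply(PROPERTY_ACCESSIONS, function(acc) {
    vals <- aaindex[[acc]]$I
    # aaindex names residues by three-letter code
    one <- vapply(names(vals), function(nm) seqinr::a(nm), character(1))
    vals[match(AA_ALPHABET, one)]
  })
  rownames(tab) <- AA_ALPHABET
  if (standardize) tab <- standardize_properties(tab)
  .property_cache[[key]] <- tab
  tab
}

.property_cache <- new.env(parent = emptyenv())

#' Standardize a property table to zero mean and unit variance per column
#'
#' Each column is centered and scaled over the 20 amino acids. Applying the
#' transformation twice gives the same result as applying it once.
#'
#' @param tab 20 x p numeric matrix of amino-acid property values.
#' @return standardized matrix of the same shape.
#' @export
standardize_properties <- function(tab) {
  stopifnot(is.matrix(tab), nrow(tab) == 20L)
  out <- scale(tab)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

# TRUE if each column has mean ~0 and sd ~1 (tolerance 1e-9)
is_standardized <- function(tab, tol = 1e-9) {
  all(abs(colMeans(tab)) <= tol) &&
    all(abs(apply(tab, 2, sd) - 1) <= tol)
}
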
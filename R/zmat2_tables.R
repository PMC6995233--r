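#' Packaged ZMAT2 pseudogene census records
#'
#' The published census of Zmat2 processed pseudogenes across mammals (with
#' the three marmoset copies from the companion primate survey): exon
#' composition, contiguity class, nucleotide identity to the mouse exons,
#' longest ORF (codons; 0 when none), amino-acid identity of the predicted
#' protein to the authentic ZMAT2, and the expression verdict from
#' RNA-sequencing library screens.
#'
#' @return data frame, one row per pseudogene copy.
#' @export
zmat2_pseudogene_table <- function() {
  path <- system.file("extdata", "zmat2_pseudogenes.tsv",
                      package = "retrocensus", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Packaged mammalian ZMAT2 protein variants
#'
#' Amino-acid identity of each mammalian ZMAT2 protein with the mouse
#' protein, with every substitution in `"X<pos>>Y"` notation (multiple
#' substitutions separated by `;`; empty when the protein is identical).
#'
#' @return data frame, one row per species (the two tandem opossum proteins
#'   appear as separate rows).
#' @export
zmat2_protein_table <- function() {
  path <- system.file("extdata", "zmat2_protein_variants.tsv",
                      package = "retrocensus", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$substitutions[is.na(df$substitutions)] <- ""
  df
}

#' Count species with an invariant protein
#'
#' Number of non-human rows in the protein-variant table carrying zero
#' substitutions relative to mouse ZMAT2.
#'
#' @param tbl table from [zmat2_protein_table()].
#' @return list: `invariant` count, `total` non-human rows.
#' @export
count_invariant_species <- function(tbl = zmat2_protein_table()) {
  nh <- tbl[tbl$species != "human", , drop = FALSE]
  list(invariant = sum(!nzchar(nh$substitutions)), total = nrow(nh))
}
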
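# shared fixtures: everything is generated in code under fixed seeds

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")

# substitute given 1-based positions of a protein with different residues
apply_subs <- function(protein, positions, to = NULL) {
  chars <- strsplit(protein, "")[[1]]
  for (k in seq_along(positions)) {
    p <- positions[k]
    repl <- if (!is.null(to)) to[k] else sample(setdiff(AA20, chars[p]), 1)
    chars[p] <- repl
  }
  paste(chars, collapse = "")
}

mutate_seq <- retrocensus:::mutate_seq

# compact mouse-like locus: same exon architecture with a shortened 3' UTR,
# used where many simulations are run
small_cfg <- function(...) {
  sim_config(exon_lengths = c(96L, 94L, 124L, 74L, 146L, 400L),
             intron_lengths = c(337L, 650L, 872L, 388L, 1234L),
             genome_length = 20000L, ...)
}

# reference exon sequences (transcript orientation) from a simulation truth
ref_exons <- function(truth, cfg) {
  cum <- cumsum(c(0L, cfg$exon_lengths))
  ex <- substring(truth$gene$mrna, cum[-length(cum)] + 1L, cum[-1])
  names(ex) <- paste0("exon", seq_along(ex))
  ex
}

# run the exon-level homology search against the simulated genome
search_exons <- function(sim, cfg, preset = scoring_preset("blastn_normal")) {
  ex <- ref_exons(sim$truth, cfg)
  do.call(rbind, lapply(names(ex), function(nm) {
    local_search(ex[[nm]], sim$genome$seq, preset,
                 query_id = nm, subject_id = sim$genome$id)
  }))
}

# reference gene model (truth coordinates) with exon sequences attached
ref_model_of <- function(sim, cfg) {
  m <- gene_model("ref", sim$genome$id, "+",
                  sim$truth$gene$exon_start, sim$truth$gene$exon_end)
  m$exon_seq <- unname(ref_exons(sim$truth, cfg))
  m$exon_index <- seq_along(m$exon_seq)
  m
}

# authentic protein encoded by the planted CDS
authentic_protein_of <- function(truth, cfg) {
  utr5 <- cfg$exon_lengths[1] - cfg$coding_span[1]
  cds_len <- cfg$coding_span[1] +
    sum(cfg$exon_lengths[-c(1, cfg$n_exons)]) + cfg$coding_span[2]
  cds <- substr(truth$gene$mrna, utr5 + 1L, utr5 + cds_len)
  sub("\\*$", "", translate_dna(cds))
}
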
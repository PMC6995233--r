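#' Configuration for the synthetic locus simulator
#'
#' Defaults emulate a mouse-like six-exon locus: exon lengths
#' 96/94/124/74/146/1774 nt with introns 337/650/872/388/1234 nt, coding
#' sequence covering the last 18 nt of exon 1, all of exons 2-5, and the
#' first 144 nt of exon 6 (600 nt, a 199-residue protein plus stop), and a
#' canonical AATAAA polyadenylation signal ending `polyA_signal_offset`
#' (default 7) nt upstream of the cleavage site.
#'
#' @param n_exons number of exons.
#' @param exon_lengths,intron_lengths nt lengths; must be consistent with
#'   `n_exons`.
#' @param coding_span length-2 integer: coding nt within the first exon
#'   (suffix) and within the last exon (prefix).
#' @param n_retrocopies number of planted retrocopies.
#' @param retro_divergence per-site substitution probability for retrocopies.
#' @param retro_truncation NULL (full length) or integer vector of exon
#'   indices retained in every retrocopy.
#' @param retro_n_gap NULL, or `c(after_exon, length)`: insert an unreadable
#'   run of N of that length between two exons of each retrocopy.
#' @param retro_insert NULL, or `c(after_exon, length)`: insert a readable
#'   foreign (random) segment of that length between two exons of each
#'   retrocopy (a mobile-element-style interruption).
#' @param duplicate logical: plant a head-to-head tandem duplicate gene,
#'   reverse-complemented immediately upstream so the two exon-1 5' ends
#'   face each other.
#' @param duplicate_divergence per-site substitution probability of the
#'   duplicate (default 0.003, i.e. ~99.7% identity).
#' @param duplicate_overlap nt of 5' overlap between the two genes.
#' @param duplicate_expression expression of the duplicate relative to the
#'   main gene (default 1/3: the main gene is the more abundant transcript).
#' @param read_length,coverage,error_rate read simulation parameters;
#'   coverage is mean reads per transcript position.
#' @param polyA_tail length of non-genomic poly-A appended to the mature
#'   transcript.
#' @param polyA_signal_offset nt between the end of the AATAAA hexamer and
#'   the cleavage site.
#' @param five_prime_low_coverage cap coverage of the first 100 transcript nt
#'   at 2 reads, keeping the two 5'-outermost ones (the sparse-5'-evidence
#'   regime seen in real libraries).
#' @param genome_length total synthetic genome length (nt).
#' @param genome_id sequence id of the synthetic genome.
#' @param seed integer seed; all stochastic draws flow from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_exons = 6L,
                       exon_lengths = c(96L, 94L, 124L, 74L, 146L, 1774L),
                       intron_lengths = c(337L, 650L, 872L, 388L, 1234L),
                       coding_span = c(18L, 144L),
                       n_retrocopies = 2L,
                       retro_divergence = 0.10,
                       retro_truncation = NULL,
                       retro_n_gap = NULL,
                       retro_insert = NULL,
                       duplicate = FALSE,
                       duplicate_divergence = 0.003,
                       duplicate_overlap = 0L,
                       duplicate_expression = 1 / 3,
                       read_length = 75L,
                       coverage = 30,
                       error_rate = 0.005,
                       polyA_tail = 30L,
                       polyA_signal_offset = 7L,
                       five_prime_low_coverage = FALSE,
                       genome_length = 40000L,
                       genome_id = "simchr1",
                       seed = 1L) {
  cfg <- list(n_exons = as.integer(n_exons),
              exon_lengths = as.integer(exon_lengths),
              intron_lengths = as.integer(intron_lengths),
              coding_span = as.integer(coding_span),
              n_retrocopies = as.integer(n_retrocopies),
              retro_divergence = retro_divergence,
              retro_truncation = if (is.null(retro_truncation)) NULL else as.integer(retro_truncation),
              retro_n_gap = if (is.null(retro_n_gap)) NULL else as.integer(retro_n_gap),
              retro_insert = if (is.null(retro_insert)) NULL else as.integer(retro_insert),
              duplicate = isTRUE(duplicate),
              duplicate_divergence = duplicate_divergence,
              duplicate_overlap = as.integer(duplicate_overlap),
              duplicate_expression = duplicate_expression,
              read_length = as.integer(read_length),
              coverage = coverage,
              error_rate = error_rate,
              polyA_tail = as.integer(polyA_tail),
              polyA_signal_offset = as.integer(polyA_signal_offset),
              five_prime_low_coverage = isTRUE(five_prime_low_coverage),
              genome_length = as.integer(genome_length),
              genome_id = genome_id,
              seed = as.integer(seed))
  if (cfg$n_exons < 1) stop("n_exons must be >= 1")
  if (length(cfg$exon_lengths) != cfg$n_exons)
    stop("exon_lengths must have n_exons entries")
  if (length(cfg$intron_lengths) != cfg$n_exons - 1L)
    stop("intron_lengths must have n_exons - 1 entries")
  if (any(cfg$exon_lengths <= 0) || any(cfg$intron_lengths <= 0))
    stop("all exon and intron lengths must be > 0")
  for (p in c(cfg$retro_divergence, cfg$duplicate_divergence, cfg$error_rate))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (cfg$read_length <= 0 || cfg$polyA_tail < 0 || cfg$genome_length <= 0)
    stop("lengths must be positive")
  if (!is.null(cfg$retro_truncation) &&
      !all(cfg$retro_truncation %in% seq_len(cfg$n_exons)))
    stop("retro_truncation must be a subset of exon indices")
  structure(cfg, class = "sim_config")
}

# substitute each position independently with probability p (always to a
# different base); N positions are left untouched
mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < p & chars != "N")
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# remove polyadenylation-signal-like hexamers from a window, keeping an
# optional planted occurrence intact
scrub_hexamers <- function(seq, keep_start = NA) {
  repeat {
    pos <- gregexpr("AATAA[AT]", seq)[[1]]
    pos <- pos[pos > 0]
    if (!is.na(keep_start)) pos <- setdiff(pos, keep_start)
    if (length(pos) == 0) return(seq)
    substr(seq, pos[1] + 2L, pos[1] + 2L) <- "C"
  }
}

# remove TATA-box / initiator consensus matches from a window (the emulated
# locus, like its biological template, carries no core promoter motifs)
scrub_promoters <- function(seq) {
  pats <- c("TATA[AT]A[AT]", "[CT][CT]A[ACGT][AT][CT][CT]")
  for (iter in 1:500) {
    pos <- unlist(lapply(pats, function(p) {
      m <- gregexpr(p, seq)[[1]]
      m[m > 0]
    }))
    if (length(pos) == 0) return(seq)
    substr(seq, pos[1] + 2L, pos[1] + 2L) <- "G"
  }
  seq
}

# random CDS: ATG + sense codons + stop, of the requested length (multiple
# of 3, >= 6); otherwise plain random DNA
random_cds <- function(len) {
  if (len < 6 || len %% 3 != 0) return(random_dna(len))
  stops <- c("TAA", "TAG", "TGA")
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- setdiff(codons, stops)
  n_mid <- len %/% 3L - 2L
  paste0("ATG", paste(sample(sense, n_mid, replace = TRUE), collapse = ""), "TAA")
}

# choose non-overlapping start positions for feature widths in [1, G],
# given already-occupied intervals; buffer nt of clearance around each
place_features <- function(G, widths, occupied = NULL, buffer = 200L) {
  starts <- integer(0)
  occ <- occupied  # list of c(start, end)
  for (w in widths) {
    if (w > G) stop("simulated features cannot fit in the genome (sizing error)")
    ok <- FALSE
    for (try in 1:2000) {
      s <- sample.int(G - w + 1L, 1)
      iv <- c(max(1L, s - buffer), min(G, s + w - 1L + buffer))
      clash <- any(vapply(occ, function(o) iv[1] <= o[2] && o[1] <= iv[2], TRUE))
      if (!clash) {
        occ <- c(occ, list(c(s, s + w - 1L)))
        starts <- c(starts, s)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("simulated features cannot fit in the genome (sizing error)")
  }
  starts
}

#' Simulate a genomic locus with planted truth
#'
#' Generates an i.i.d.-uniform background genome and plants: the multi-exon
#' gene (splice-site GT..AG dinucleotides at intron ends, a coding ORF, and
#' an AATAAA signal upstream of the 3' cleavage site); optionally a
#' head-to-head tandem duplicate on the opposite strand immediately upstream
#' of exon 1; and intronless retrocopies of the mature mRNA, mutated at the
#' configured per-site rate, inserted at non-overlapping positions on random
#' strands. The 50 nt upstream of the cleavage site are scrubbed of
#' competing AATAAA/AATAAT hexamers so the planted signal is the proximal
#' one.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [seq_record()]) and `truth` (a `sim_truth`
#'   list recording every planted coordinate).
#' @export
simulate_locus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ne <- config$n_exons
  el <- config$exon_lengths
  il <- config$intron_lengths

  # ---- gene sequence in gene-local coordinates (1 = exon 1 start) ----
  utr5 <- el[1] - config$coding_span[1]
  utr3 <- el[ne] - config$coding_span[2]
  if (utr5 < 0 || utr3 < 0) stop("coding_span exceeds terminal exon lengths")
  cds_len <- config$coding_span[1] + sum(el[setdiff(seq_len(ne), c(1L, ne))]) +
    config$coding_span[2]
  cds <- random_cds(cds_len)
  mrna <- paste0(random_dna(utr5), cds, random_dna(utr3))
  # exon local coordinates
  ex_start <- integer(ne); ex_end <- integer(ne)
  pos <- 1L
  introns <- character(ne - 1L)
  for (j in seq_len(ne)) {
    ex_start[j] <- pos
    ex_end[j] <- pos + el[j] - 1L
    pos <- ex_end[j] + 1L
    if (j < ne) {
      i_seq <- random_dna(il[j])
      substr(i_seq, 1L, 2L) <- "GT"
      substr(i_seq, il[j] - 1L, il[j]) <- "AG"
      introns[j] <- i_seq
      pos <- pos + il[j]
    }
  }
  gene_len <- ex_end[ne]
  # plant the poly-A signal and scrub competitors in the proximal window
  off <- config$polyA_signal_offset
  if (el[ne] < off + 6L + 50L) stop("last exon too short for the poly-A signal window")
  mr_len <- nchar(mrna)
  sig_start_mrna <- mr_len - off - 5L
  win_start <- mr_len - 49L
  win <- substr(mrna, win_start, mr_len)
  win <- scrub_hexamers(win, keep_start = NA)
  substr(win, sig_start_mrna - win_start + 1L, sig_start_mrna - win_start + 6L) <- "AATAAA"
  win <- scrub_hexamers(win, keep_start = sig_start_mrna - win_start + 1L)
  substr(mrna, win_start, mr_len) <- win
  # assemble gene from (possibly scrubbed) exon pieces
  cum <- cumsum(c(0L, el))
  exon_seq <- substring(mrna, cum[seq_len(ne)] + 1L, cum[seq_len(ne) + 1L])
  parts <- character(0)
  for (j in seq_len(ne)) {
    parts <- c(parts, exon_seq[j], if (j < ne) introns[j])
  }
  gene_seq <- paste(parts, collapse = "")
  stopifnot(nchar(gene_seq) == gene_len)

  # ---- duplicate (head-to-head, reverse complement, upstream) ----
  dup <- NULL
  dup_width <- 0L
  v <- config$duplicate_overlap
  if (config$duplicate) {
    dup_seq_local <- mutate_seq(gene_seq, config$duplicate_divergence)
    dup_width <- gene_len - v
    if (dup_width < 0) stop("duplicate_overlap exceeds gene length")
  }

  # ---- retrocopies ----
  retro <- list()
  if (config$n_retrocopies > 0) {
    keep <- if (is.null(config$retro_truncation)) seq_len(ne) else sort(config$retro_truncation)
    for (r in seq_len(config$n_retrocopies)) {
      rseq <- paste(exon_seq[keep], collapse = "")
      gap <- config$retro_n_gap
      ins <- config$retro_insert
      split_after <- if (!is.null(gap)) gap else ins
      if (!is.null(split_after)) {
        filler <- if (!is.null(gap)) strrep("N", gap[2]) else
          random_dna(ins[2])
        k <- which(keep == split_after[1])
        if (length(k) == 1 && k < length(keep)) {
          before <- paste(exon_seq[keep[seq_len(k)]], collapse = "")
          after <- paste(exon_seq[keep[(k + 1L):length(keep)]], collapse = "")
          rseq <- paste0(before, filler, after)
        }
      }
      rseq <- mutate_seq(rseq, config$retro_divergence)
      strand <- sample(c("+", "-"), 1)
      retro[[r]] <- list(id = sprintf("retro%d", r), strand = strand,
                         exons = keep, divergence = config$retro_divergence,
                         seq_local = rseq,
                         gap = if (is.null(gap)) NULL else gap)
    }
  }

  # ---- placement ----
  G <- config$genome_length
  widths <- c(dup_width + gene_len,
              vapply(retro, function(r) nchar(r$seq_local), 0L))
  starts <- place_features(G, widths)
  genome <- random_dna(G)
  block_start <- starts[1]
  gstart <- block_start + dup_width
  substr(genome, gstart, gstart + gene_len - 1L) <- gene_seq
  # identifiability guard: the genome must not continue the poly-A run past
  # the cleavage site, or junction reads could not pin down the exact end
  ce <- gstart + gene_len - 1L
  if (ce < G) {
    k <- leading_a(substr(genome, ce + 1L, min(G, ce + 10L)))
    if (k > 0) substr(genome, ce + 1L, ce + k) <- strrep("C", k)
  }
  # emulate the promoter-less locus: no TATA/Inr consensus within 100 nt
  # upstream of the TSS (skipped when the duplicate occupies that region)
  if (!config$duplicate && gstart > 1L) {
    lo <- max(1L, gstart - 106L)
    substr(genome, lo, gstart - 1L) <-
      scrub_promoters(substr(genome, lo, gstart - 1L))
  }
  dup_truth <- NULL
  if (config$duplicate) {
    ins <- revcomp(substr(dup_seq_local, v + 1L, gene_len))
    if (dup_width > 0)
      substr(genome, block_start, block_start + dup_width - 1L) <- ins
    # gene-local position x maps to genome position gstart + v - x
    map <- function(x) gstart + v - x
    dup_mrna <- paste(substring(dup_seq_local, ex_start, ex_end), collapse = "")
    dup_truth <- list(id = "gene2", strand = "-",
                      exon_start = as.integer(map(ex_end)),
                      exon_end = as.integer(map(ex_start)),
                      divergence = config$duplicate_divergence,
                      overlap = v, mrna = dup_mrna)
  }
  retro_truth <- list()
  for (r in seq_along(retro)) {
    s <- starts[r + 1L]
    rc <- retro[[r]]
    w <- nchar(rc$seq_local)
    ins <- if (rc$strand == "+") rc$seq_local else revcomp(rc$seq_local)
    substr(genome, s, s + w - 1L) <- ins
    retro_truth[[r]] <- list(id = rc$id, start = s, end = s + w - 1L,
                             strand = rc$strand, exons = rc$exons,
                             divergence = rc$divergence,
                             gap = rc$gap, seq = rc$seq_local)
  }

  truth <- structure(list(
    genome_id = config$genome_id,
    genome_length = G,
    seed = config$seed,
    gene = list(id = "gene1", strand = "+",
                exon_start = as.integer(gstart - 1L + ex_start),
                exon_end = as.integer(gstart - 1L + ex_end),
                coding_start = as.integer(gstart - 1L + ex_start[1] + utr5),
                coding_end = as.integer(gstart - 1L + ex_end[ne] - utr3),
                tss = as.integer(gstart),
                cleavage = as.integer(gstart - 1L + gene_len),
                polyA_signal_start = as.integer(gstart - 1L + gene_len - off - 5L),
                polyA_signal_end = as.integer(gstart - 1L + gene_len - off),
                signal_offset = off,
                mrna = mrna),
    duplicate = dup_truth,
    retrocopies = retro_truth,
    expression = list(gene1 = 1,
                      gene2 = if (config$duplicate) config$duplicate_expression else 0)
  ), class = "sim_truth")

  list(genome = seq_record(config$genome_id, genome, "synthetic locus"),
       truth = truth)
}

#' Simulate RNA-seq reads from the planted transcripts
#'
#' Samples single-end reads uniformly along each mature transcript (exons
#' joined, introns absent) with a non-genomic poly-A tail appended, so reads
#' crossing the cleavage site carry poly-A and no read extends past the true
#' 5' end. Read counts per transcript are Poisson with mean
#' `coverage * mRNA_length / read_length`, scaled by the configured relative
#' expression for the duplicate gene. Sequencing errors are i.i.d.
#' substitutions. Qualities are constant Phred 40 ("I").
#'
#' @param truth a `sim_truth` from [simulate_locus()].
#' @param config the same [sim_config()] (read-model parameters are taken
#'   from it; the read RNG stream is derived from `config$seed`).
#' @return a data frame of reads (`id`, `seq`, `qual`) with attribute
#'   `counts` naming the per-transcript read counts.
#' @export
simulate_reads <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  transcripts <- list(gene1 = truth$gene$mrna)
  weights <- c(gene1 = 1)
  if (!is.null(truth$duplicate)) {
    transcripts$gene2 <- truth$duplicate$mrna
    weights["gene2"] <- config$duplicate_expression
  }
  rl <- config$read_length
  out <- list()
  counts <- integer(0)
  for (tn in names(transcripts)) {
    mr <- transcripts[[tn]]
    tseq <- paste0(mr, strrep("A", config$polyA_tail))
    if (rl > nchar(tseq))
      stop("read_length exceeds transcript length (sizing error)")
    lambda <- config$coverage * weights[[tn]] * nchar(mr) / rl
    n <- rpois(1, lambda)
    counts[tn] <- n
    if (n == 0) next
    starts <- sample.int(nchar(tseq) - rl + 1L, n, replace = TRUE)
    if (config$five_prime_low_coverage) {
      # sparse 5' regime: at most 2 reads over the first 100 transcript nt,
      # retaining the two 5'-outermost ("longest clone") reads
      in5 <- which(starts <= 100L)
      if (length(in5) > 2) {
        drop <- setdiff(in5, in5[order(starts[in5])][1:2])
        starts <- starts[-drop]
        counts[tn] <- length(starts)
      }
    }
    seqs <- substring(tseq, starts, starts + rl - 1L)
    if (config$error_rate > 0) {
      seqs <- vapply(seqs, mutate_seq, "", p = config$error_rate,
                     USE.NAMES = FALSE)
    }
    out[[tn]] <- data.frame(
      id = sprintf("%s_read%05d", tn, seq_along(seqs)),
      seq = seqs, qual = strrep("I", rl), stringsAsFactors = FALSE)
  }
  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(id = character(), seq = character(), qual = character(),
               stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  attr(reads, "counts") <- counts
  class(reads) <- c("sim_reads", class(reads))
  reads
}
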
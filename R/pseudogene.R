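STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame
#'
#' Longest ATG-initiated, stop-terminated reading frame in any of the six
#' frames (both strands by default; retrocopies insert in either
#' orientation). The reported codon count excludes the stop codon. Frames
#' shorter than `min_codons` yield an empty result (the census prints
#' "none").
#'
#' @param dna DNA string.
#' @param min_codons minimum ORF length to report (codons, default 30).
#' @param both_strands scan the reverse complement too.
#' @return list: `codons` (0 when none), `protein`, `strand`, `start`,
#'   `end` (1-based nucleotide coordinates on the given strand's sequence,
#'   including the stop codon).
#' @export
longest_orf <- function(dna, min_codons = 30L, both_strands = TRUE) {
  dna <- toupper(if (inherits(dna, "seq_record")) dna$seq else dna)
  best <- list(codons = 0L, protein = "", strand = NA_character_,
               start = NA_integer_, end = NA_integer_)
  for (st in if (both_strands) c("+", "-") else "+") {
    s <- if (st == "+") dna else revcomp(dna)
    n <- nchar(s)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3L
      if (ncod < 2) next
      codons <- substring(s, f + seq(1L, by = 3L, length.out = ncod),
                          f + seq(3L, by = 3L, length.out = ncod))
      stops <- which(codons %in% STOP_CODONS)
      prev <- 0L
      for (sp in stops) {
        if (sp - prev >= 2L) {
          atg <- which(codons[(prev + 1L):(sp - 1L)] == "ATG")
          if (length(atg) > 0) {
            a <- prev + atg[1]
            len <- sp - a
            if (len > best$codons) {
              aa <- Biostrings::GENETIC_CODE[codons[a:(sp - 1L)]]
              aa[is.na(aa)] <- "X"
              best <- list(codons = len, protein = paste(aa, collapse = ""),
                           strand = st,
                           start = f + 3L * (a - 1L) + 1L,
                           end = f + 3L * sp)
            }
          }
        }
        prev <- sp
      }
    }
  }
  if (best$codons < min_codons)
    return(list(codons = 0L, protein = "", strand = NA_character_,
                start = NA_integer_, end = NA_integer_))
  best
}

#' Compare a predicted pseudogene protein to the authentic protein
#'
#' Globally aligns the two proteins, reports percent identity
#' (terminal-gaps-excluded, one decimal) and every substitution in
#' `"X<pos>>Y"` notation with positions numbered on the authentic protein.
#'
#' @param predicted,authentic protein strings (non-empty).
#' @return list: `pident`, `substitutions` (character vector, possibly
#'   empty), `n_substitutions`, `alignment` (the `global_alignment`).
#' @export
protein_report <- function(predicted, authentic) {
  stopifnot(nchar(predicted) > 0, nchar(authentic) > 0)
  al <- global_align(authentic, predicted)
  a <- strsplit(al$aligned_a, "")[[1]]  # authentic
  b <- strsplit(al$aligned_b, "")[[1]]  # predicted
  pos <- 0L
  subs <- character(0)
  for (k in seq_along(a)) {
    if (a[k] != "-") pos <- pos + 1L
    if (a[k] != "-" && b[k] != "-" && a[k] != b[k]) {
      subs <- c(subs, sprintf("%s%d>%s", a[k], pos, b[k]))
    }
  }
  list(pident = al$pident, substitutions = subs,
       n_substitutions = length(subs), alignment = al)
}

#' Classify a pseudogene candidate
#'
#' Takes the unchained exon-labeled hit cluster(s) of one candidate and
#' assigns its exon composition and contiguity class: `"fragmented"` when
#' exons lie on different sequences, `"gapped"` when an unreadable N-run or
#' a readable foreign insertion splits the exon run (`gap_kind` records
#' which), `"partial"` for a proper exon subset, `"full_length"` otherwise.
#' A cluster overlapping an accepted gene model is rejected with a reason.
#'
#' @param clusters one `alignment_hits` data frame, or a list of them (for
#'   candidates spread over several sequences).
#' @param reference reference [gene_model()] (exon count, exon sequences).
#' @param genome_seq named character vector of subject sequences (names are
#'   seqids), or a single string.
#' @param accepted_models optional list of [gene_model()]s; overlapping
#'   candidates are rejected.
#' @param authentic_protein optional authentic protein string for the
#'   protein-level report.
#' @param min_intron unreadable (N-run) gaps at or above this (nt) split the
#'   exon run.
#' @param insertion_min readable gaps at or above this (nt) count as foreign
#'   insertions; shorter readable gaps are treated as diverged spacer within
#'   a continuous copy (alignment edges fray at high divergence).
#' @param min_orf_codons [longest_orf()] threshold.
#' @return a `pseudogene_record` list.
#' @export
classify_candidate <- function(clusters, reference, genome_seq,
                               accepted_models = NULL,
                               authentic_protein = NULL,
                               min_intron = 50L, insertion_min = 100L,
                               min_orf_codons = 30L) {
  if (is.data.frame(clusters)) clusters <- list(clusters)
  hits <- do.call(rbind, lapply(clusters, as.data.frame))
  if (!"exon" %in% names(hits)) hits$exon <- hit_exon_index(hits$query_id)
  seqids <- unique(hits$subject_id)
  # rejection against accepted gene models
  for (m in accepted_models) {
    ov <- hits$subject_id == m$seqid &
      hits$s_start <= max(m$exon_end) & hits$s_end >= min(m$exon_start)
    if (any(ov)) {
      return(structure(list(status = "rejected",
                            reason = sprintf("overlaps gene model %s",
                                             m$gene_id)),
                       class = "pseudogene_record"))
    }
  }
  getseq <- function(sid) {
    if (length(genome_seq) == 1 && is.null(names(genome_seq))) genome_seq
    else genome_seq[[sid]]
  }
  ne <- length(reference$exon_seq)
  exons <- sort(unique(hits$exon))
  # best hit per exon for the identity table
  ident <- vapply(exons, function(e) {
    max(hits$pident[hits$exon == e])
  }, 0)
  names(ident) <- paste0("exon", exons)
  strand <- names(which.max(table(hits$strand)))

  gap_kind <- "none"
  contiguity <- NULL
  if (length(seqids) > 1) {
    contiguity <- "fragmented"
  } else {
    h <- hits[order(hits$s_start), , drop = FALSE]
    gaps <- if (nrow(h) > 1) h$s_start[-1] - h$s_end[-nrow(h)] - 1L else integer(0)
    big <- which(gaps >= min_intron)
    kinds <- character(0)
    if (length(big) > 0) {
      gseq <- getseq(seqids)
      ref_mrna <- if (!is.null(reference$exon_seq))
        paste(reference$exon_seq, collapse = "") else NULL
      # transcript-likeness of a readable gap: best local score per base
      # (a diverged exon that merely failed seeding still aligns locally)
      gap_score_ok <- function(gs) {
        if (is.null(ref_mrna)) return(FALSE)
        if (strand == "-") gs <- revcomp(gs)
        gs <- gsub("N", "", gs)
        if (nchar(gs) < 20) return(FALSE)
        loc <- cpp_local_align(gs, ref_mrna, 2L, -3L, 5L, 2L)
        loc$score >= 0.5 * nchar(gs)
      }
      for (i in big) {
        gs <- substr(gseq, h$s_end[i] + 1L, h$s_start[i + 1] - 1L)
        nfrac <- if (nchar(gs) == 0) 0 else
          sum(strsplit(gs, "")[[1]] == "N") / nchar(gs)
        kind <- if (nfrac >= 0.5) "n_run"
          else if (nchar(gs) < insertion_min || gap_score_ok(gs)) "spacer"
          else "insertion"
        if (kind == "spacer") {
          # an exon skipped across a transcript-like spacer is present even
          # though its own hit fell below the seeding threshold
          skipped <- setdiff(seq(min(h$exon[i], h$exon[i + 1]),
                                 max(h$exon[i], h$exon[i + 1])),
                             c(h$exon[i], h$exon[i + 1]))
          if (length(skipped) > 0 && gap_score_ok(gs)) {
            exons <- sort(union(exons, skipped))
          }
        } else {
          kinds <- c(kinds, kind)
        }
      }
    }
    if (length(kinds) > 0) {
      contiguity <- "gapped"
      gap_kind <- if ("n_run" %in% kinds) "n_run" else "insertion"
    } else if (length(exons) < ne) {
      contiguity <- "partial"
    } else {
      contiguity <- "full_length"
    }
  }
  start <- min(hits$s_start); end <- max(hits$s_end)
  region <- if (length(seqids) == 1) substr(getseq(seqids), start, end) else NA
  orf <- if (!is.na(region[1]))
    longest_orf(region, min_codons = min_orf_codons) else
    list(codons = 0L, protein = "")
  prot_id <- NA_real_; subs <- character(0)
  if (orf$codons > 0 && !is.null(authentic_protein)) {
    pr <- protein_report(orf$protein, authentic_protein)
    prot_id <- pr$pident
    subs <- pr$substitutions
  }
  structure(list(status = "ok",
                 id = sprintf("psi_%s_%d", seqids[1], start),
                 seqid = seqids, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 exons_present = exons, contiguity = contiguity,
                 gap_kind = gap_kind, exon_identity = ident,
                 orf_codons = orf$codons, protein = orf$protein,
                 protein_identity = prot_id, substitutions = subs,
                 expressed = "untestable"),
            class = "pseudogene_record")
}

#' @export
print.pseudogene_record <- function(x, ...) {
  if (x$status == "rejected") {
    cat("<pseudogene_record> rejected:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<pseudogene_record %s> exons %s, %s%s, ORF %s, expressed: %s\n",
              x$id, paste(x$exons_present, collapse = ","), x$contiguity,
              if (x$gap_kind != "none") paste0(" (", x$gap_kind, ")") else "",
              if (x$orf_codons > 0) paste0(x$orf_codons, " codons") else "none",
              x$expressed))
  invisible(x)
}

#' Build single-nucleotide discriminating probe pairs
#'
#' For each isolated difference between two near-identical sequences,
#' returns a probe pair: one `probe_len`-mer per variant centered on the
#' differing position (shifted only near sequence ends). Pairs are emitted
#' only where the window contains no other difference, so each pair differs
#' at exactly one position.
#'
#' @param seq_a,seq_b near-identical DNA (or transcript) strings.
#' @param probe_len probe length (default 60).
#' @return data frame: `pos_a`, `pos_b` (differing position in each
#'   sequence), `probe_a`, `probe_b`, `offset` (position of the difference
#'   within the probe). Zero rows, with a warning, when the sequences are
#'   identical.
#' @export
make_discriminating_probes <- function(seq_a, seq_b, probe_len = 60L) {
  al <- global_align(seq_a, seq_b)
  a <- strsplit(al$aligned_a, "")[[1]]
  b <- strsplit(al$aligned_b, "")[[1]]
  diffcol <- which(a != b)
  if (length(diffcol) == 0) {
    warning("sequences are identical: no discriminating probes")
    return(data.frame(pos_a = integer(), pos_b = integer(),
                      probe_a = character(), probe_b = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  }
  pos_a <- cumsum(a != "-")
  pos_b <- cumsum(b != "-")
  half <- probe_len %/% 2L
  rows <- list()
  for (cc in diffcol) {
    if (a[cc] == "-" || b[cc] == "-") next
    lo <- cc - (half - 1L); hi <- cc + half
    if (lo < 1L) { hi <- hi - lo + 1L; lo <- 1L }
    if (hi > length(a)) { lo <- lo - (hi - length(a)); hi <- length(a) }
    if (lo < 1L) next  # alignment shorter than the probe
    wincols <- lo:hi
    if (any(wincols != cc & (a[wincols] != b[wincols]))) next  # not isolated
    rows[[length(rows) + 1L]] <- data.frame(
      pos_a = pos_a[cc], pos_b = pos_b[cc],
      probe_a = paste(a[wincols], collapse = ""),
      probe_b = paste(b[wincols], collapse = ""),
      offset = cc - lo + 1L, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(pos_a = integer(), pos_b = integer(),
                      probe_a = character(), probe_b = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# exact-substring read count for one probe (either orientation)
exact_probe_count <- function(probe, reads) {
  if (nrow(reads) == 0) return(0L)
  rc <- revcomp(probe)
  sum(grepl(probe, reads$seq, fixed = TRUE) |
        grepl(rc, reads$seq, fixed = TRUE))
}

#' Test pseudogene expression with discriminating probes
#'
#' Builds single-nucleotide discriminating probe pairs between the
#' authentic transcript and the candidate's exonic sequence, counts reads
#' matching each variant probe exactly (exact substring matching -- the
#' only regime in which single-nucleotide discrimination is sound), and
#' applies positive-control logic: the candidate is called unexpressed only
#' when the authentic probes are detected and the candidate probes are not.
#'
#' @param authentic_seq authentic transcript (or exon concatenation).
#' @param candidate_seq candidate pseudogene exonic sequence.
#' @param reads read data frame (`seq` column); reads must be at least
#'   `probe_len` long to be informative.
#' @param probe_len probe length.
#' @return list: `expressed` (`"yes"`, `"no"` or `"untestable"`),
#'   `authentic_count`, `candidate_count`, `probes`.
#' @export
expression_test <- function(authentic_seq, candidate_seq, reads,
                            probe_len = 60L) {
  probes <- suppressWarnings(
    make_discriminating_probes(authentic_seq, candidate_seq, probe_len))
  if (nrow(reads) == 0 || nrow(probes) == 0) {
    return(list(expressed = "untestable", authentic_count = 0L,
                candidate_count = 0L, probes = probes))
  }
  ac <- sum(vapply(probes$probe_a, exact_probe_count, 0L, reads = reads))
  cc <- sum(vapply(probes$probe_b, exact_probe_count, 0L, reads = reads))
  expressed <- if (cc > 0) "yes" else if (ac > 0) "no" else "untestable"
  list(expressed = expressed, authentic_count = as.integer(ac),
       candidate_count = as.integer(cc), probes = probes)
}

# parse an exon-composition string like "1-6", "4-6", "2,3" or "6"
parse_exons <- function(x) {
  unlist(lapply(strsplit(x, ",")[[1]], function(p) {
    p <- trimws(p)
    if (grepl("-", p)) {
      r <- as.integer(strsplit(p, "-")[[1]])
      seq(r[1], r[2])
    } else as.integer(p)
  }))
}

#' Full-length census rule
#'
#' A pseudogene is censused as full-length when all reference exons are
#' present at a single locus (not fragmented across sequences, not a
#' partial exon subset) and no unreadable N-run interrupts the exon run. A
#' readable mobile-element insertion does not demote an otherwise complete
#' copy.
#'
#' @param tbl census table (see [census()]).
#' @param n_ref_exons number of exons in the reference gene.
#' @return logical vector over rows of `tbl`.
#' @export
full_length_filter <- function(tbl, n_ref_exons = 6L) {
  all6 <- vapply(tbl$exons_present, function(x)
    length(parse_exons(x)) == n_ref_exons &&
      all(seq_len(n_ref_exons) %in% parse_exons(x)), TRUE, USE.NAMES = FALSE)
  all6 & tbl$contiguity != "fragmented" & tbl$contiguity != "partial" &
    tbl$gap_kind != "n_run"
}

#' Pseudogene census
#'
#' Collates classified records into a census table (exon composition,
#' contiguity, identities, ORF, expression) and applies
#' [full_length_filter()] to select the subset carried into the phylogeny.
#'
#' @param records list of `pseudogene_record`s, or an already-tabular data
#'   frame with the census columns.
#' @param n_ref_exons number of exons in the reference gene.
#' @return list: `table` (data frame with a `full_length` column) and
#'   `full_length` (ids passing the filter).
#' @export
census <- function(records, n_ref_exons = 6L) {
  if (is.data.frame(records)) {
    tbl <- records
  } else {
    records <- Filter(function(r) r$status == "ok", records)
    if (length(records) == 0) {
      tbl <- data.frame(id = character(), species = character(),
                        exons_present = character(), contiguity = character(),
                        gap_kind = character(), nt_identity = character(),
                        orf_codons = integer(), aa_identity = numeric(),
                        expressed = character(), stringsAsFactors = FALSE)
    } else {
      tbl <- do.call(rbind, lapply(records, function(r) {
        data.frame(
          id = r$id,
          species = if (!is.null(r$species)) r$species else NA_character_,
          exons_present = paste(collapse_runs(r$exons_present), collapse = ","),
          contiguity = r$contiguity, gap_kind = r$gap_kind,
          nt_identity = paste(sprintf("%.1f", r$exon_identity), collapse = ","),
          orf_codons = r$orf_codons,
          aa_identity = r$protein_identity,
          expressed = r$expressed, stringsAsFactors = FALSE)
      }))
    }
  }
  if (nrow(tbl) == 0) {
    tbl$full_length <- logical(0)
    return(list(table = tbl, full_length = character(0)))
  }
  tbl$full_length <- full_length_filter(tbl, n_ref_exons)
  ids <- if ("id" %in% names(tbl)) tbl$id[tbl$full_length] else
    rownames(tbl)[tbl$full_length]
  list(table = tbl, full_length = ids)
}

# collapse sorted integers into run strings: c(1:6) -> "1-6"; c(2,3) -> "2-3"
collapse_runs <- function(x) {
  x <- sort(unique(x))
  if (length(x) == 0) return(character(0))
  br <- cumsum(c(1L, diff(x) != 1L))
  vapply(split(x, br), function(r) {
    if (length(r) == 1) as.character(r) else paste0(r[1], "-", r[length(r)])
  }, "")
}
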
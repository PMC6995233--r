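#' Gene model
#'
#' Ordered exon intervals (5' to 3') on one strand of one sequence, with the
#' coding sub-interval of each exon. Exons must be non-overlapping and
#' strictly ordered along the strand, introns at least 1 nt, and the mRNA
#' length is by construction the sum of exon lengths.
#'
#' @param gene_id id string.
#' @param seqid subject sequence id.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end genomic exon intervals, given 5' to 3' along
#'   the transcript (for `"-"` strand models, descending genomic order).
#' @param coding optional two-column matrix of per-exon coding sub-intervals
#'   (NA rows for wholly non-coding exons).
#' @param exon_seq optional character vector of exon sequences in transcript
#'   orientation.
#' @return a `gene_model`.
#' @export
gene_model <- function(gene_id, seqid, strand, exon_start, exon_end,
                       coding = NULL, exon_seq = NULL) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_start) == length(exon_end),
            all(exon_start <= exon_end))
  n <- length(exon_start)
  gs <- if (strand == "+") exon_start else rev(exon_start)
  ge <- if (strand == "+") exon_end else rev(exon_end)
  if (n > 1) {
    if (any(diff(gs) <= 0) || any(gs[-1] - ge[-n] < 2))
      stop("exons must be non-overlapping and strictly ordered with introns >= 1 nt")
  }
  intron_lengths <- if (n > 1) as.integer(gs[-1] - ge[-n] - 1L) else integer(0)
  structure(list(gene_id = gene_id, seqid = seqid, strand = strand,
                 exon_start = as.integer(exon_start),
                 exon_end = as.integer(exon_end),
                 exon_lengths = as.integer(exon_end - exon_start + 1L),
                 intron_lengths = intron_lengths,
                 span = as.integer(max(ge) - min(gs) + 1L),
                 mrna_length = as.integer(sum(exon_end - exon_start + 1L)),
                 coding = coding, exon_seq = exon_seq),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s> %s:%d-%d (%s), %d exons, span %d nt, mRNA %d nt\n",
              x$gene_id, x$seqid, min(x$exon_start), max(x$exon_end),
              x$strand, length(x$exon_start), x$span, x$mrna_length))
  invisible(x)
}

# extract exon sequences (transcript orientation) from a genome string
model_exon_seqs <- function(model, genome_seq) {
  s <- substring(genome_seq, model$exon_start, model$exon_end)
  if (model$strand == "-") s <- revcomp(s)
  s
}

# exon index encoded in a hit's query id ("exon3" -> 3)
hit_exon_index <- function(query_id) {
  as.integer(sub("^.*?(\\d+)$", "\\1", query_id))
}

#' Chain exon-level hits into gene models
#'
#' Groups hits by subject and strand, clusters them along the subject, and
#' chains clusters whose exons appear in transcript order with gaps within
#' `[min_intron, max_intron]` into [gene_model()]s. Clusters whose
#' inter-exon gaps are all below `min_intron` are intronless retrocopy
#' candidates and are returned unchained, as are clusters interrupted by
#' unreadable (N-run) gaps. Competing chains over the same region are
#' resolved by exon count, then summed score, then leftmost position.
#'
#' @param hits an `alignment_hits` data frame whose `query_id`s end in the
#'   reference exon number (e.g. `"exon1"` ... `"exon6"`).
#' @param reference the reference [gene_model()] (supplies exon count and
#'   coding layout).
#' @param genome_seq subject genome string (used to check gap readability
#'   and splice-site dinucleotides).
#' @param min_intron,max_intron allowed intron length range (nt); gaps below
#'   `min_intron` mark a cluster as intronless.
#' @return list with `models` (list of `gene_model`, with a `splice_qc`
#'   attribute flagging non-GT..AG introns) and `clusters` (list of
#'   unchained hit data frames for the pseudogene stage).
#' @export
chain_hits <- function(hits, reference, genome_seq,
                       min_intron = 50L, max_intron = 50000L) {
  out <- list(models = list(), clusters = list())
  if (is.null(hits) || nrow(hits) == 0) return(out)
  hits$exon <- hit_exon_index(hits$query_id)
  models <- list()
  clusters <- list()
  for (sid in unique(hits$subject_id)) {
    for (str in c("+", "-")) {
      h <- hits[hits$subject_id == sid & hits$strand == str, , drop = FALSE]
      if (nrow(h) == 0) next
      h <- h[order(h$s_start), , drop = FALSE]
      # new cluster where the locus gap is exceeded or the exon order
      # resets (e.g. a retrocopy upstream of the gene on the same strand)
      gap_break <- diff(h$s_start) > max_intron
      ord_break <- if (str == "+") diff(h$exon) <= 0L else diff(h$exon) >= 0L
      grp <- cumsum(c(1L, gap_break | ord_break))
      for (g in unique(grp)) {
        cl <- h[grp == g, , drop = FALSE]
        # best hit per exon within the cluster
        cl <- do.call(rbind, lapply(split(cl, cl$exon), function(d)
          d[which.max(d$score), , drop = FALSE]))
        cl <- cl[order(cl$s_start), , drop = FALSE]
        # transcript order along the subject
        ord_ok <- if (str == "+") !is.unsorted(cl$exon, strictly = TRUE)
                  else !is.unsorted(rev(cl$exon), strictly = TRUE)
        gaps <- if (nrow(cl) > 1) cl$s_start[-1] - cl$s_end[-nrow(cl)] - 1L
                else integer(0)
        gap_seqs <- if (length(gaps)) substring(genome_seq,
                                                cl$s_end[-nrow(cl)] + 1L,
                                                cl$s_start[-1] - 1L)
                    else character(0)
        n_frac <- vapply(gap_seqs, function(s) {
          if (nchar(s) == 0) 0 else
            sum(strsplit(s, "")[[1]] == "N") / nchar(s)
        }, 0, USE.NAMES = FALSE)
        genic <- ord_ok && nrow(cl) > 1 &&
          all(gaps >= min_intron & gaps <= max_intron) && all(n_frac < 0.5)
        if (genic) {
          es <- cl$s_start; ee <- cl$s_end
          if (str == "-") { es <- rev(es); ee <- rev(ee) }
          m <- gene_model(sprintf("model_%s_%d", sid, length(models) + 1L),
                          sid, str, es, ee)
          m$exon_index <- sort(cl$exon)
          m$score <- sum(cl$score)
          m$exon_seq <- model_exon_seqs(m, genome_seq)
          # splice-site QC: GT..AG at intron boundaries (reported, not enforced)
          ispl <- character(0)
          if (nrow(cl) > 1) {
            left <- substring(genome_seq, cl$s_end[-nrow(cl)] + 1L,
                              cl$s_end[-nrow(cl)] + 2L)
            right <- substring(genome_seq, cl$s_start[-1] - 2L,
                               cl$s_start[-1] - 1L)
            ispl <- if (str == "+") paste0(left, "..", right)
                    else rev(paste0(revcomp(right), "..", revcomp(left)))
          }
          m$splice_qc <- all(ispl == "GT..AG")
          models[[length(models) + 1L]] <- m
        } else {
          attr(cl, "intronless") <- nrow(cl) > 1 && length(gaps) > 0 &&
            all(gaps < min_intron)
          clusters[[length(clusters) + 1L]] <- cl
        }
      }
    }
  }
  # resolve overlapping competing chains: more exons > higher score > leftmost
  if (length(models) > 1) {
    ord <- order(-vapply(models, function(m) length(m$exon_start), 0L),
                 -vapply(models, function(m) m$score, 0),
                 vapply(models, function(m) min(m$exon_start), 0L))
    models <- models[ord]
    keep <- rep(TRUE, length(models))
    for (i in seq_along(models)) {
      if (!keep[i]) next
      for (j in seq_along(models)) {
        if (i == j || !keep[j]) next
        a <- models[[i]]; b <- models[[j]]
        if (a$seqid == b$seqid && a$strand == b$strand &&
            min(b$exon_start) <= max(a$exon_end) &&
            min(a$exon_start) <= max(b$exon_end) && j > i) {
          keep[j] <- FALSE
        }
      }
    }
    models <- models[keep]
  }
  list(models = models, clusters = clusters)
}

#' Detect tandem duplication at a locus
#'
#' Reports a duplication when two gene models lie within `max_distance` of
#' each other and share at least `min_shared_exons` exon-level components,
#' and states the orientation relation: `"divergent"` (head-to-head, 5' ends
#' facing), `"convergent"` (3' ends facing) or `"tandem-same-strand"`.
#' Per-exon identity between the two models is computed by [global_align()].
#'
#' @param models list of [gene_model()]s with exon sequences attached.
#' @param max_distance maximum separation (nt) between models (default 20 kb).
#' @param min_shared_exons exon-sharing threshold for the duplication flag.
#' @return a `locus_report` list: `models`, `duplicated`, `orientation`,
#'   `exon_identity` (named numeric), `distance`.
#' @export
detect_duplication <- function(models, max_distance = 20000L,
                               min_shared_exons = 4L) {
  stopifnot(length(models) >= 1)
  rep0 <- structure(list(models = models, duplicated = FALSE,
                         orientation = NA_character_,
                         exon_identity = NULL, distance = NA_integer_),
                    class = "locus_report")
  if (length(models) < 2) return(rep0)
  # consider the two highest-scoring models on the same sequence
  pair <- NULL
  for (i in seq_along(models)) {
    for (j in seq_along(models)) {
      if (j <= i) next
      a <- models[[i]]; b <- models[[j]]
      if (a$seqid != b$seqid) next
      d <- max(0L, max(min(a$exon_start), min(b$exon_start)) -
                 min(max(a$exon_end), max(b$exon_end)))
      shared <- length(intersect(a$exon_index, b$exon_index))
      if (d <= max_distance && shared >= min_shared_exons) {
        pair <- list(a = a, b = b, distance = d)
        break
      }
    }
    if (!is.null(pair)) break
  }
  if (is.null(pair)) return(rep0)
  a <- pair$a; b <- pair$b
  left <- if (min(a$exon_start) <= min(b$exon_start)) a else b
  right <- if (identical(left, a)) b else a
  orientation <- if (left$strand == right$strand) "tandem-same-strand"
    else if (left$strand == "-" && right$strand == "+") "divergent"
    else "convergent"
  shared <- intersect(a$exon_index, b$exon_index)
  ident <- vapply(shared, function(e) {
    sa <- a$exon_seq[match(e, a$exon_index)]
    sb <- b$exon_seq[match(e, b$exon_index)]
    global_align(sa, sb)$pident
  }, 0)
  names(ident) <- paste0("exon", shared)
  structure(list(models = models, duplicated = TRUE,
                 orientation = orientation, exon_identity = ident,
                 distance = pair$distance),
            class = "locus_report")
}

#' @export
print.locus_report <- function(x, ...) {
  if (x$duplicated) {
    cat(sprintf("Locus: %d gene models; duplication detected (%s, %d nt apart)\n",
                length(x$models), x$orientation, x$distance))
  } else {
    cat(sprintf("Locus: %d gene model(s); no duplication\n", length(x$models)))
  }
  invisible(x)
}

#' Gene metrics row
#'
#' Exon and intron lengths, total genomic span, mRNA length (sum of exon
#' lengths) and the codon count of the coding concatenation (excluding the
#' stop codon). A coding length not divisible by 3 raises a warning flag in
#' the row rather than an error.
#'
#' @param model a [gene_model()].
#' @param coding_length optional coding length (nt) if not derivable from
#'   the model's `coding` matrix.
#' @return a one-row data frame.
#' @export
gene_metrics <- function(model, coding_length = NULL) {
  if (is.null(coding_length)) {
    coding_length <- if (!is.null(model$coding))
      sum(model$coding[, 2] - model$coding[, 1] + 1L, na.rm = TRUE)
    else NA_integer_
  }
  codons <- NA_integer_
  frame_warning <- FALSE
  if (!is.na(coding_length)) {
    if (coding_length %% 3L != 0L) frame_warning <- TRUE
    codons <- coding_length %/% 3L - 1L  # excludes the stop codon
  }
  n <- length(model$exon_lengths)
  row <- data.frame(gene_id = model$gene_id, seqid = model$seqid,
                    strand = model$strand, n_exons = n,
                    span = model$span, mrna_length = model$mrna_length,
                    coding_length = coding_length, codons = codons,
                    frame_warning = frame_warning, stringsAsFactors = FALSE)
  row$exon_lengths <- paste(model$exon_lengths, collapse = ",")
  row$intron_lengths <- paste(model$intron_lengths, collapse = ",")
  row
}

#' Per-exon identity table against a reference
#'
#' For each model, each exon present is globally aligned to the matching
#' reference exon and percent identity reported; exons aligned over less
#' than the full reference exon are annotated with the aligned length
#' (`"96.7 (31 bp)"` style). Missing exons are marked absent.
#'
#' @param reference reference [gene_model()] with `exon_seq`.
#' @param others list of [gene_model()]s with `exon_seq` and `exon_index`.
#' @return a data frame of formatted cells, with numeric matrices in
#'   attributes `identity` and `aligned_length`.
#' @export
exon_identity_table <- function(reference, others) {
  ne <- length(reference$exon_seq)
  idm <- matrix(NA_real_, nrow = length(others), ncol = ne)
  alm <- matrix(NA_integer_, nrow = length(others), ncol = ne)
  cells <- matrix("absent", nrow = length(others), ncol = ne)
  for (i in seq_along(others)) {
    m <- others[[i]]
    idx <- if (!is.null(m$exon_index)) m$exon_index else seq_along(m$exon_seq)
    for (k in seq_along(idx)) {
      e <- idx[k]
      if (e > ne) next
      al <- global_align(reference$exon_seq[e], m$exon_seq[k])
      idm[i, e] <- al$pident
      alm[i, e] <- al$columns
      cells[i, e] <- if (al$columns < nchar(reference$exon_seq[e]))
        sprintf("%.1f (%d bp)", al$pident, al$columns)
      else sprintf("%.1f", al$pident)
    }
  }
  df <- as.data.frame(cells, stringsAsFactors = FALSE)
  names(df) <- paste0("exon", seq_len(ne))
  df <- cbind(data.frame(gene_id = vapply(others, function(m) m$gene_id, ""),
                         stringsAsFactors = FALSE), df)
  attr(df, "identity") <- idm
  attr(df, "aligned_length") <- alm
  df
}
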
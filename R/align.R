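#' BLAST-style scoring presets
#'
#' Two presets mirror the classic nucleotide search parameterizations:
#' `"blastn_normal"` (match +1, mismatch -3, gap open 5, gap extend 2,
#' word size 11) used for genome-scale homology search, and `"megablast"`
#' (match +2, mismatch -3, same gaps and word size) optimized for highly
#' similar sequences such as read-vs-probe queries. A gap of length L costs
#' `gap_open + L * gap_extend`. No E-value is computed; `min_score` is the
#' minimum reportable raw score standing in for an E-value cutoff.
#'
#' @param name preset name, `"blastn_normal"` or `"megablast"`.
#' @param match,mismatch,gap_open,gap_extend,word_size,min_score overrides.
#' @return a `scoring_preset` list.
#' @export
scoring_preset <- function(name = c("megablast", "blastn_normal"),
                           match = NULL, mismatch = NULL,
                           gap_open = NULL, gap_extend = NULL,
                           word_size = NULL, min_score = NULL) {
  name <- match.arg(name)
  def <- switch(name,
    megablast     = list(match = 2L, mismatch = -3L, gap_open = 5L,
                         gap_extend = 2L, word_size = 11L, min_score = 40L),
    blastn_normal = list(match = 1L, mismatch = -3L, gap_open = 5L,
                         gap_extend = 2L, word_size = 11L, min_score = 20L))
  p <- list(name = name,
            match = if (is.null(match)) def$match else as.integer(match),
            mismatch = if (is.null(mismatch)) def$mismatch else as.integer(mismatch),
            gap_open = if (is.null(gap_open)) def$gap_open else as.integer(gap_open),
            gap_extend = if (is.null(gap_extend)) def$gap_extend else as.integer(gap_extend),
            word_size = if (is.null(word_size)) def$word_size else as.integer(word_size),
            min_score = if (is.null(min_score)) def$min_score else as.integer(min_score))
  if (p$word_size < 4) stop("word_size must be >= 4")
  if (p$gap_open < 0 || p$gap_extend < 0) stop("gap penalties must be >= 0")
  structure(p, class = "scoring_preset")
}

#' DUST-like low-complexity masking
#'
#' Slides a window over the sequence and masks (with N) windows whose
#' triplet-composition score exceeds the threshold, in the spirit of the
#' DUST filter applied by nucleotide search tools.
#'
#' @param seq DNA string.
#' @param window window width in nt.
#' @param threshold score above which the window is masked.
#' @return the sequence with low-complexity windows replaced by N.
#' @export
dust_mask <- function(seq, window = 64, threshold = 2) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3) return(seq)
  chars <- strsplit(seq, "")[[1]]
  tri <- paste0(chars[seq_len(n - 2)], chars[seq_len(n - 2) + 1L],
                chars[seq_len(n - 2) + 2L])
  masked <- rep(FALSE, n)
  starts <- seq(1, max(1, n - window + 1), by = max(1, window %/% 2))
  for (s in starts) {
    e <- min(n, s + window - 1)
    idx <- s:max(s, e - 2)
    ct <- table(tri[idx])
    score <- sum(ct * (ct - 1) / 2) / max(1, length(idx) - 1)
    if (score > threshold) masked[s:e] <- TRUE
  }
  if (any(masked)) {
    chars[masked] <- "N"
    seq <- paste(chars, collapse = "")
  }
  seq
}

# statistics of an alignment string pair: columns exclude terminal gaps
aln_stats <- function(aligned_a, aligned_b) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  if (length(a) != length(b)) stop("aligned strings differ in length")
  both <- which(a != "-" & b != "-")
  if (length(both) == 0) stop("zero aligned columns: identity undefined")
  cols <- seq(min(both), max(both))
  matches <- sum(a[cols] == b[cols] & a[cols] != "-")
  list(matches = matches, columns = length(cols),
       pident = round_half_up(100 * matches / length(cols), 1))
}

#' Percent identity of an alignment
#'
#' Matches divided by aligned columns, terminal gaps excluded, rounded
#' half-up to one decimal -- the convention of per-exon and per-protein
#' identity tables.
#'
#' @param x an alignment object (a hit row, or a `global_alignment`), or an
#'   aligned string when `y` is given.
#' @param y optional second aligned string.
#' @return numeric percent identity in `[0, 100]`.
#' @export
percent_identity <- function(x, y = NULL) {
  if (!is.null(y)) return(aln_stats(x, y)$pident)
  if (inherits(x, "global_alignment")) {
    return(aln_stats(x$aligned_a, x$aligned_b)$pident)
  }
  if (is.data.frame(x)) {
    return(vapply(seq_len(nrow(x)), function(i)
      aln_stats(x$aligned_query[i], x$aligned_subject[i])$pident, 0))
  }
  stop("unsupported input to percent_identity()")
}

# recompute an affine-gap score from alignment strings (invariant checking)
rescore_alignment <- function(aligned_a, aligned_b, scoring) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  score <- 0L
  in_gap <- 0L  # 0 none, 1 gap in a, 2 gap in b
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      side <- if (a[k] == "-") 1L else 2L
      if (in_gap != side) score <- score - scoring$gap_open
      score <- score - scoring$gap_extend
      in_gap <- side
    } else {
      in_gap <- 0L
      score <- score +
        if (a[k] == b[k] && a[k] != "N") scoring$match else scoring$mismatch
    }
  }
  score
}

empty_hits <- function(status = "ok") {
  df <- data.frame(query_id = character(), subject_id = character(),
                   q_start = integer(), q_end = integer(),
                   s_start = integer(), s_end = integer(),
                   strand = character(), score = integer(),
                   pident = numeric(), length = integer(),
                   aligned_query = character(), aligned_subject = character(),
                   stringsAsFactors = FALSE)
  attr(df, "status") <- status
  class(df) <- c("alignment_hits", class(df))
  df
}

#' Seed-and-extend local DNA search
#'
#' Finds local alignments of a query against both strands of a subject via
#' exact `word_size` seeds, grouped into diagonal bands and extended with
#' affine-gap Smith-Waterman dynamic programming over a window around each
#' band. Hits below `preset$min_score` are dropped; hits whose query and
#' subject intervals are contained in a better hit are merged away. Hits are
#' sorted by score (descending), ties by subject start (ascending). Subject
#' intervals are always reported in forward-strand coordinates; minus-strand
#' hits mean the reverse complement of the query matched.
#'
#' @param query,subject DNA strings (or length-1 named character vectors; the
#'   name is used as the id).
#' @param preset a [scoring_preset()].
#' @param query_id,subject_id ids used in the output.
#' @param mask apply [dust_mask()] to the query before seeding (default TRUE).
#' @param band_tolerance diagonal slack when grouping seeds into one band.
#' @param margin extra subject context (nt) around each band window.
#' @return an `alignment_hits` data frame; if the query is shorter than the
#'   word size, an empty result with attribute `status = "no_seed_possible"`.
#' @export
local_search <- function(query, subject, preset = scoring_preset("megablast"),
                         query_id = NULL, subject_id = NULL, mask = TRUE,
                         band_tolerance = 50L, margin = 100L) {
  if (is.null(query_id)) query_id <- if (!is.null(names(query))) names(query)[1] else "query"
  if (is.null(subject_id)) subject_id <- if (!is.null(names(subject))) names(subject)[1] else "subject"
  query <- check_dna(unname(query[1]), "query")
  subject <- check_dna(unname(subject[1]), "subject")
  qlen <- nchar(query)
  if (qlen < preset$word_size) {
    return(empty_hits(status = "no_seed_possible"))
  }
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    qseed <- if (mask) dust_mask(q) else q
    seeds <- cpp_find_seeds(qseed, subject, preset$word_size)
    if (nrow(seeds) == 0) next
    diag <- seeds[, "spos"] - seeds[, "qpos"]
    ord <- order(diag, seeds[, "spos"])
    diag <- diag[ord]
    seeds <- seeds[ord, , drop = FALSE]
    grp <- cumsum(c(1L, diff(diag) > band_tolerance))
    for (g in unique(grp)) {
      sel <- seeds[grp == g, , drop = FALSE]
      ws <- max(1L, min(sel[, "spos"]) - max(sel[, "qpos"]) - margin)
      we <- min(nchar(subject),
                max(sel[, "spos"]) + preset$word_size - 1L +
                  (qlen - min(sel[, "qpos"])) + margin)
      res <- cpp_local_align(q, substr(subject, ws, we),
                             preset$match, preset$mismatch,
                             preset$gap_open, preset$gap_extend)
      if (res$score < preset$min_score) next
      st <- aln_stats(res$aligned_a, res$aligned_b)
      if (strand == "+") {
        q1 <- res$a_start; q2 <- res$a_end
      } else {
        q1 <- qlen - res$a_end + 1L; q2 <- qlen - res$a_start + 1L
      }
      hits[[length(hits) + 1L]] <- data.frame(
        query_id = query_id, subject_id = subject_id,
        q_start = q1, q_end = q2,
        s_start = res$b_start + ws - 1L, s_end = res$b_end + ws - 1L,
        strand = strand, score = res$score, pident = st$pident,
        length = st$columns,
        aligned_query = res$aligned_a, aligned_subject = res$aligned_b,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) return(empty_hits())
  df <- do.call(rbind, hits)
  df <- unique(df)
  # containment merge: drop hits nested inside a better-or-equal hit
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j || !keep[i]) next
      if (df$strand[i] == df$strand[j] && df$score[i] <= df$score[j] &&
          df$s_start[i] >= df$s_start[j] && df$s_end[i] <= df$s_end[j] &&
          df$q_start[i] >= df$q_start[j] && df$q_end[i] <= df$q_end[j] &&
          !(df$s_start[i] == df$s_start[j] && df$s_end[i] == df$s_end[j] &&
            df$q_start[i] == df$q_start[j] && df$q_end[i] == df$q_end[j] &&
            i < j)) {
        keep[i] <- FALSE
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(-df$score, df$s_start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "status") <- "ok"
  class(df) <- c("alignment_hits", class(df))
  df
}

# slim seed-gated local alignment for inner loops (read-vs-probe counting):
# no masking, no data-frame assembly; returns NULL when no seed/score
slim_local <- function(q, subject, preset) {
  best <- NULL
  qlen <- nchar(q)
  for (strand in c("+", "-")) {
    qq <- if (strand == "+") q else revcomp(q)
    if (nrow(cpp_find_seeds(qq, subject, preset$word_size)) == 0) next
    res <- cpp_local_align(qq, subject, preset$match, preset$mismatch,
                           preset$gap_open, preset$gap_extend)
    if (res$score < preset$min_score) next
    if (is.null(best) || res$score > best$score) {
      if (strand == "-") {
        tmp <- res$a_start
        res$a_start <- qlen - res$a_end + 1L
        res$a_end <- qlen - tmp + 1L
      }
      res$strand <- strand
      best <- res
    }
  }
  best
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' Optimal global alignment of two sequences of the same molecule type, with
#' a deterministic traceback (ties resolved match/mismatch first, then gap
#' in `a`, then gap in `b`). Percent identity follows the
#' terminal-gaps-excluded rule of [percent_identity()].
#'
#' @param a,b sequences (DNA or protein; both must be the same type).
#' @param match,mismatch,gap_open,gap_extend scoring; defaults depend on the
#'   molecule type (DNA: +2/-3, gaps 5/2; protein: +2/-1, gaps 10/1).
#' @return a `global_alignment` list: `score`, `aligned_a`, `aligned_b`,
#'   `pident`, `matches`, `columns`.
#' @export
global_align <- function(a, b, match = NULL, mismatch = NULL,
                         gap_open = NULL, gap_extend = NULL) {
  a <- toupper(unname(a[1])); b <- toupper(unname(b[1]))
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  ta <- guess_moltype(a); tb <- guess_moltype(b)
  if (ta != tb) stop("mixed molecule types: ", ta, " vs ", tb)
  if (ta == "dna") {
    if (is.null(match)) match <- 2L
    if (is.null(mismatch)) mismatch <- -3L
    if (is.null(gap_open)) gap_open <- 5L
    if (is.null(gap_extend)) gap_extend <- 2L
  } else {
    if (is.null(match)) match <- 2L
    if (is.null(mismatch)) mismatch <- -1L
    if (is.null(gap_open)) gap_open <- 10L
    if (is.null(gap_extend)) gap_extend <- 1L
  }
  res <- cpp_global_align(a, b, as.integer(match), as.integer(mismatch),
                          as.integer(gap_open), as.integer(gap_extend))
  st <- aln_stats(res$aligned_a, res$aligned_b)
  structure(list(score = res$score, aligned_a = res$aligned_a,
                 aligned_b = res$aligned_b, pident = st$pident,
                 matches = st$matches, columns = st$columns,
                 moltype = ta,
                 scoring = list(match = match, mismatch = mismatch,
                                gap_open = gap_open, gap_extend = gap_extend)),
            class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: score %d, identity %.1f%% (%d/%d columns)\n",
              x$score, x$pident, x$matches, x$columns))
  invisible(x)
}
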
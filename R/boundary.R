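#' Tile 60-bp probes outward from an anchor
#'
#' Adjacent, non-overlapping 60-nt genomic probes labeled a, b, c, ...
#' extending outward from the anchor: upstream for the 5' side (tile a ends
#' at the anchor), downstream for the 3' side (tile a starts at the anchor).
#' Tiles that would run off the sequence are dropped with a warning; every
#' returned tile is exactly 60 nt.
#'
#' @param genome a [seq_record()] or DNA string.
#' @param anchor 1-based genomic coordinate inside the transcript.
#' @param side `"five_prime"` or `"three_prime"`.
#' @param n_tiles number of probes requested.
#' @param tile_len probe length (nt).
#' @return data frame: `label`, `start`, `end`, `side`, `seq`.
#' @export
tile_probes <- function(genome, anchor, side = c("five_prime", "three_prime"),
                        n_tiles = 6L, tile_len = 60L) {
  side <- match.arg(side)
  gseq <- if (inherits(genome, "seq_record")) genome$seq else check_dna(genome)
  G <- nchar(gseq)
  if (anchor < 1 || anchor > G) stop("anchor outside the sequence")
  k <- seq_len(n_tiles) - 1L
  if (side == "five_prime") {
    end <- anchor - k * tile_len
    start <- end - tile_len + 1L
  } else {
    start <- anchor + k * tile_len
    end <- start + tile_len - 1L
  }
  ok <- start >= 1L & end <= G
  if (!all(ok)) {
    warning(sprintf("%d of %d probes run off the sequence and were dropped",
                    sum(!ok), n_tiles))
  }
  start <- start[ok]; end <- end[ok]
  if (length(start) == 0) {
    return(data.frame(label = character(), start = integer(),
                      end = integer(), side = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  data.frame(label = letters[seq_along(start)],
             start = as.integer(start), end = as.integer(end), side = side,
             seq = substring(gseq, start, end), stringsAsFactors = FALSE)
}

#' Count reads supporting a probe
#'
#' A read supports a probe when its best local alignment to the probe
#' (megablast scoring, both strands) covers at least `min_cover` of the
#' probe positions at `min_identity` percent identity or better. The count
#' is deterministic and monotone non-increasing in `min_identity`.
#'
#' @param reads data frame with a `seq` column.
#' @param probe one row of [tile_probes()] output (or a 60-nt string).
#' @param preset [scoring_preset()] used for the alignment.
#' @param min_cover minimum aligned probe positions.
#' @param min_identity minimum percent identity of the alignment.
#' @return integer count of supporting reads.
#' @export
count_support <- function(reads, probe,
                          preset = scoring_preset("megablast", min_score = 30),
                          min_cover = 50L, min_identity = 90) {
  pseq <- if (is.data.frame(probe)) probe$seq[1] else probe
  n <- 0L
  for (rs in reads$seq) {
    best <- slim_local(pseq, rs, preset)
    if (is.null(best)) next
    st <- aln_stats(best$aligned_a, best$aligned_b)
    if ((best$a_end - best$a_start + 1L) >= min_cover &&
        st$pident >= min_identity) n <- n + 1L
  }
  n
}

# read-count profile over a set of tiles
probe_profile <- function(reads, tiles, ...) {
  tiles$count <- vapply(seq_len(nrow(tiles)), function(i)
    count_support(reads, tiles[i, , drop = FALSE], ...), 0L)
  tiles
}

#' Scan for polyadenylation signals upstream of a cleavage site
#'
#' Finds all AATAAA and AATAAT hexamers ending within `window` nt upstream
#' of (and including) the candidate cleavage site, ordered by proximity to
#' it; the canonical AATAAA ranks first at equal distance.
#'
#' @param seq DNA string (e.g. the genome).
#' @param cleavage 1-based candidate cleavage coordinate.
#' @param window search window (nt) upstream of the cleavage site.
#' @return data frame: `motif`, `start`, `end`, `distance` (cleavage minus
#'   motif end); zero rows when no signal is present.
#' @export
scan_polyA <- function(seq, cleavage, window = 50L) {
  gseq <- if (inherits(seq, "seq_record")) seq$seq else toupper(seq)
  lo <- max(1L, cleavage - window + 1L)
  region <- substr(gseq, lo, cleavage)
  out <- list()
  for (motif in c("AATAAA", "AATAAT")) {
    pos <- gregexpr(motif, region, fixed = TRUE)[[1]]
    pos <- pos[pos > 0]
    for (p in pos) {
      st <- lo + p - 1L
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, start = st, end = st + 5L,
        distance = cleavage - (st + 5L), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), distance = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[df$distance >= 0, , drop = FALSE]
  df[order(df$distance, df$motif != "AATAAA"), , drop = FALSE]
}

#' Scan for core promoter motifs upstream of a 5' call
#'
#' Matches the TATA-box consensus (TATAWAW) and the initiator consensus
#' (YYANWYY) within `window` nt upstream of the candidate transcription
#' start.
#'
#' @param seq DNA string.
#' @param pos candidate 5'-end coordinate.
#' @param window search window (nt).
#' @return data frame: `motif_class`, `start`, `motif`.
#' @export
scan_promoter <- function(seq, pos, window = 100L) {
  gseq <- if (inherits(seq, "seq_record")) seq$seq else toupper(seq)
  lo <- max(1L, pos - window)
  region <- substr(gseq, lo, pos - 1L)
  pats <- c(TATA = "TATA[AT]A[AT]", Inr = "[CT][CT]A[ACGTN][AT][CT][CT]")
  out <- list()
  for (cls in names(pats)) {
    m <- gregexpr(pats[[cls]], region)[[1]]
    starts <- m[m > 0]
    lens <- attr(m, "match.length")[m > 0]
    for (k in seq_along(starts)) {
      out[[length(out) + 1L]] <- data.frame(
        motif_class = cls, start = lo + starts[k] - 1L,
        motif = substr(region, starts[k], starts[k] + lens[k] - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(motif_class = character(), start = integer(),
                      motif = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$start), , drop = FALSE]
}

# trailing A-run length of a read
trailing_a <- function(x) {
  m <- regmatches(x, regexpr("A+$", x))
  if (length(m) == 0) 0L else nchar(m)
}

#' Call a transcript end from read evidence
#'
#' Computes a tiled read-count profile outward from the anchor, then:
#' for the 3' side, takes reads bearing at least `min_tail` trailing
#' non-genomic A's, aligns their tail-trimmed bodies to the genomic region
#' and calls the cleavage site as the modal genomic junction, with the
#' nearest upstream polyadenylation signal and its distance reported; if no
#' poly-A junction reads exist, the outermost aligned base of reads
#' supporting the outermost non-zero tile is used ("longest clone" rule)
#' with confidence `"tentative"`. For the 5' side, the longest-clone rule
#' applies directly, and the call is `"tentative"` unless a promoter motif
#' lies within 100 nt upstream. An all-zero profile yields a no-call result
#' with explicit status.
#'
#' @param genome a [seq_record()] or DNA string.
#' @param reads data frame with a `seq` column.
#' @param anchor coordinate inside the transcript near the sought end (e.g.
#'   the edge of the annotated terminal exon's coding region).
#' @param side `"five_prime"` or `"three_prime"`.
#' @param n_tiles number of 60-nt probes.
#' @param min_tail minimum trailing non-genomic A's for poly-A junction
#'   evidence.
#' @param signal_window [scan_polyA()] window.
#' @param preset probe-support scoring.
#' @return a `boundary_call` list: `side`, `status`, `coordinate`,
#'   `evidence`, `confidence`, `polyA` (motif/start/end/distance or NULL),
#'   `profile`.
#' @export
call_end <- function(genome, reads, anchor,
                     side = c("five_prime", "three_prime"),
                     n_tiles = 6L, min_tail = 8L, signal_window = 50L,
                     preset = scoring_preset("megablast", min_score = 30)) {
  side <- match.arg(side)
  gseq <- if (inherits(genome, "seq_record")) genome$seq else check_dna(genome)
  tiles <- tile_probes(gseq, anchor, side, n_tiles = n_tiles)
  profile <- probe_profile(reads, tiles, preset = preset)
  no_call <- structure(list(side = side, status = "no_call",
                            coordinate = NA_integer_, evidence = NA_character_,
                            confidence = NA_character_, polyA = NULL,
                            profile = profile),
                       class = "boundary_call")
  if (nrow(profile) == 0 || all(profile$count == 0)) return(no_call)
  outer_idx <- max(which(profile$count > 0))
  region_pad <- if (side == "three_prime") 3000L else 400L
  region_lo <- max(1L, min(tiles$start, anchor) - 400L)
  region_hi <- min(nchar(gseq), max(tiles$end, anchor) + region_pad)
  region <- substr(gseq, region_lo, region_hi)

  if (side == "three_prime") {
    junctions <- integer(0)
    for (rs in reads$seq) {
      tl <- trailing_a(rs)
      if (tl < min_tail) next
      body <- substr(rs, 1L, nchar(rs) - tl)
      if (nchar(body) < 20L) next
      best <- slim_local(body, region, preset)
      if (is.null(best) || best$strand != "+") next
      lag <- nchar(body) - best$a_end
      if (lag > 2L) next  # alignment must reach the tail junction
      junction <- best$b_end + lag + region_lo - 1L
      # trailing A's that match the genome are parsimoniously genomic: the
      # junction extends through them, and only the remainder is tail
      cont <- substr(gseq, junction + 1L, junction + tl)
      genomic_a <- leading_a(cont)
      if (tl - genomic_a < min_tail) next
      junctions <- c(junctions, junction + genomic_a)
    }
    if (length(junctions) > 0) {
      tab <- table(junctions)
      coord <- as.integer(names(tab)[which.max(tab)])
      sig <- scan_polyA(gseq, coord, window = signal_window)
      polyA <- if (nrow(sig) > 0) as.list(sig[1, ]) else NULL
      return(structure(list(side = side, status = "called",
                            coordinate = coord, evidence = "polyA-junction",
                            confidence = "supported", polyA = polyA,
                            profile = profile), class = "boundary_call"))
    }
    # fall back to the longest-clone rule
    coord <- outermost_read_end(reads, profile, outer_idx, region, region_lo,
                                side)
    sig <- if (!is.na(coord)) scan_polyA(gseq, coord, window = signal_window)
           else scan_polyA(gseq, anchor, window = signal_window)[0, ]
    polyA <- if (nrow(sig) > 0) as.list(sig[1, ]) else NULL
    return(structure(list(side = side, status = "called", coordinate = coord,
                          evidence = "longest-read end",
                          confidence = "tentative", polyA = polyA,
                          profile = profile), class = "boundary_call"))
  }

  # five_prime
  coord <- outermost_read_end(reads, profile, outer_idx, region, region_lo,
                              side)
  if (is.na(coord)) return(no_call)
  prom <- scan_promoter(gseq, coord, window = 100L)
  conf <- if (nrow(prom) > 0) "supported" else "tentative"
  structure(list(side = side, status = "called", coordinate = coord,
                 evidence = "longest-read end", confidence = conf,
                 polyA = NULL, profile = profile, promoter = prom),
            class = "boundary_call")
}

# leading A-run length (how far a poly-A run continues into the genome)
leading_a <- function(x) {
  nchar(regmatches(x, regexpr("^A*", x)))
}

# outermost aligned genomic base among reads supporting the outermost
# non-zero tile
outermost_read_end <- function(reads, profile, outer_idx, region, region_lo,
                               side) {
  tile <- profile[outer_idx, ]
  preset <- scoring_preset("megablast", min_score = 30)
  coords <- integer(0)
  for (rs in reads$seq) {
    # seed gate against the tile itself: supporting reads must share a word
    if (nrow(cpp_find_seeds(rs, tile$seq, preset$word_size)) == 0 &&
        nrow(cpp_find_seeds(revcomp(rs), tile$seq, preset$word_size)) == 0)
      next
    best <- slim_local(rs, region, preset)
    if (is.null(best) || best$strand != "+") next
    s1 <- best$b_start + region_lo - 1L
    s2 <- best$b_end + region_lo - 1L
    # must overlap the outermost supported tile
    if (s1 <= tile$end && tile$start <= s2) {
      coords <- c(coords, if (side == "five_prime") s1 else s2)
    }
  }
  if (length(coords) == 0) return(NA_integer_)
  if (side == "five_prime") min(coords) else max(coords)
}

#' @export
print.boundary_call <- function(x, ...) {
  if (x$status != "called") {
    cat(sprintf("<boundary_call %s> no call (all probes unsupported)\n", x$side))
    return(invisible(x))
  }
  cat(sprintf("<boundary_call %s> position %d (%s, %s)\n", x$side,
              x$coordinate, x$evidence, x$confidence))
  if (!is.null(x$polyA)) {
    cat(sprintf("  poly-A signal %s at %d-%d, %d nt upstream of cleavage\n",
                x$polyA$motif, x$polyA$start, x$polyA$end, x$polyA$distance))
  }
  invisible(x)
}
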
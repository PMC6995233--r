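#' Sequence record
#'
#' A minimal container for one sequence: id, residues, free-text description.
#' Residues are uppercased; DNA records admit A/C/G/T/N only (unreadable
#' segments are runs of N), protein records the amino-acid alphabet plus X.
#'
#' @param id record id (no whitespace).
#' @param seq residue string.
#' @param desc description (may be empty).
#' @param moltype `"dna"` or `"protein"`; guessed from the alphabet if NULL.
#' @return a `seq_record` list.
#' @export
seq_record <- function(id, seq, desc = "", moltype = NULL) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  seq <- toupper(seq)
  if (nchar(seq) == 0) stop("residues must be non-empty")
  if (is.null(moltype)) moltype <- guess_moltype(seq)
  if (moltype == "dna") {
    seq <- check_dna(seq, paste0("record '", id, "'"))
  } else if (grepl("[^ABCDEFGHIKLMNPQRSTVWXYZ*]", seq)) {
    stop("record '", id, "' contains illegal protein characters")
  }
  structure(list(id = id, desc = desc, seq = seq, moltype = moltype),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s> %s (%d %s)\n", x$id,
              if (nzchar(x$desc)) x$desc else "", nchar(x$seq),
              if (x$moltype == "dna") "nt" else "aa"))
  invisible(x)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings. Residues are normalized to uppercase on
#' read; DNA records are validated against the A/C/G/T/N alphabet.
#'
#' @param path file path.
#' @param moltype `"dna"` or `"protein"`.
#' @return `read_fasta`: a named list of [seq_record()]s.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                 error = function(e) stop("FASTA parse error: ",
                                          conditionMessage(e)))
  if (length(ss) == 0) stop("FASTA parse error: no records in ", path)
  nm <- names(ss)
  nm <- sub("\r$", "", nm)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  recs <- lapply(seq_along(ss), function(i) {
    seq_record(id[i], gsub("\r", "", as.character(ss[[i]])), desc[i],
               moltype = moltype)
  })
  names(recs) <- id
  recs
}

#' @param records a list of [seq_record()]s (or a single one).
#' @param width line width for wrapping.
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  ss <- Biostrings::BStringSet(vapply(records, function(r) r$seq, ""))
  names(ss) <- vapply(records, function(r)
    if (nzchar(r$desc)) paste(r$id, r$desc) else r$id, "")
  Biostrings::writeXStringSet(ss, path, format = "fasta", width = width)
  invisible(path)
}

#' Read / write FASTQ (Phred+33)
#'
#' @param path file path.
#' @return `read_fastq`: a data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) | seq_along(lines) %% 4 != 1]
  if (length(lines) == 0 || length(lines) %% 4 != 0)
    stop("FASTQ parse error: record count is not a multiple of 4 lines")
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  if (!all(startsWith(ids, "@")) || !all(startsWith(plus, "+")))
    stop("FASTQ parse error: malformed record headers")
  if (any(nchar(seqs) != nchar(quals)))
    stop("FASTQ parse error: sequence and quality lengths differ")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("FASTQ parse error: illegal characters in read ",
                     sub("^@", "", ids[which(bad)[1]]))
  data.frame(id = sub("^@", "", ids), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence and quality lengths differ")
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  }
  invisible(path)
}

#' Genomic features
#'
#' Features are plain data frames with columns `seqid`, `source`, `type`,
#' `start`, `end`, `strand`, `ID`, `Parent`, `Name` (1-based inclusive
#' coordinates, the convention used throughout the package).
#'
#' @param seqid,type,start,end,strand,ID,Parent,Name,source vectors, recycled.
#' @return a feature data frame.
#' @export
feature_frame <- function(seqid, type, start, end, strand = "+",
                          ID = NA_character_, Parent = NA_character_,
                          Name = NA_character_, source = "retrocensus") {
  df <- data.frame(seqid = seqid, source = source, type = type,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, ID = ID, Parent = Parent, Name = Name,
                   stringsAsFactors = FALSE)
  bad <- df$start < 1 | df$end < df$start
  if (any(bad)) stop("invalid feature coordinates: need 1 <= start <= end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df
}

#' Read / write GFF3
#'
#' Wrappers over rtracklayer; the GFF3 version pragma is emitted and
#' coordinates are 1-based inclusive.
#'
#' @param features a [feature_frame()].
#' @param path file path.
#' @return `read_gff3`: a feature data frame.
#' @export
write_gff3 <- function(features, path) {
  bad <- features$start < 1 | features$end < features$start
  if (any(bad)) stop("invalid feature coordinates: need 1 <= start <= end")
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$source <- features$source
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- features$ID
  S4Vectors::mcols(gr)$Parent <- features$Parent
  S4Vectors::mcols(gr)$Name <- features$Name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  flat <- function(x) {
    if (is.null(x)) return(NA_character_)
    x <- vapply(as.list(x), function(e)
      if (length(e) == 0) NA_character_ else paste(e, collapse = ","), "")
    x
  }
  mc <- S4Vectors::mcols(gr)
  getcol <- function(nm) {
    if (nm %in% names(mc)) {
      v <- mc[[nm]]
      if (methods::is(v, "List")) flat(v) else as.character(v)
    } else rep(NA_character_, length(gr))
  }
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    source = getcol("source"),
    type = as.character(mc$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = getcol("ID"), Parent = getcol("Parent"), Name = getcol("Name"),
    stringsAsFactors = FALSE)
}

#' Write / read a Newick tree
#'
#' @param tree an `ape::phylo` tree (internal node labels, when present, are
#'   written as support values).
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Serialize / restore the planted-truth ledger
#'
#' The truth from [simulate_locus()] round-trips losslessly through JSON.
#'
#' @param truth a `sim_truth`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  structure(x, class = "sim_truth")
}

#' Express planted truth as GFF3-ready features
#'
#' @param truth a `sim_truth`.
#' @return a [feature_frame()] with gene, mRNA, exon and pseudogene rows.
#' @export
truth_to_features <- function(truth) {
  g <- truth$gene
  rows <- list(
    feature_frame(truth$genome_id, "gene", min(g$exon_start), max(g$exon_end),
                  "+", ID = g$id, Name = g$id),
    feature_frame(truth$genome_id, "mRNA", min(g$exon_start), max(g$exon_end),
                  "+", ID = paste0(g$id, ".t1"), Parent = g$id),
    feature_frame(truth$genome_id, "exon", g$exon_start, g$exon_end, "+",
                  ID = sprintf("%s.e%d", g$id, seq_along(g$exon_start)),
                  Parent = paste0(g$id, ".t1")))
  if (!is.null(truth$duplicate)) {
    d <- truth$duplicate
    rows <- c(rows, list(
      feature_frame(truth$genome_id, "gene", min(d$exon_start),
                    max(d$exon_end), "-", ID = d$id, Name = d$id),
      feature_frame(truth$genome_id, "exon", d$exon_start, d$exon_end, "-",
                    ID = sprintf("%s.e%d", d$id, seq_along(d$exon_start)),
                    Parent = d$id)))
  }
  for (r in truth$retrocopies) {
    rows <- c(rows, list(
      feature_frame(truth$genome_id, "pseudogene", r$start, r$end, r$strand,
                    ID = r$id, Name = r$id)))
  }
  do.call(rbind, rows)
}
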
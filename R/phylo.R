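#' Reference-anchored multiple alignment
#'
#' Aligns every sequence to the reference with [global_align()] and
#' projects the pairwise alignments onto reference coordinates; insertions
#' relative to the reference are merged into shared columns, left-aligned.
#' Sequences under `min_identity` percent identity to the reference are
#' excluded with a warning.
#'
#' @param sequences named character vector of DNA sequences.
#' @param reference reference DNA string.
#' @param min_identity exclusion threshold (percent).
#' @param ref_label row name used for the reference (NULL to omit the
#'   reference row).
#' @return character matrix (rows = taxa, columns = alignment columns, gap
#'   = `"-"`).
#' @export
anchored_msa <- function(sequences, reference, min_identity = 50,
                         ref_label = NULL) {
  stopifnot(!is.null(names(sequences)), all(nzchar(names(sequences))))
  reference <- toupper(unname(reference[1]))
  L <- nchar(reference)
  subs <- list(); inss <- list()
  for (nm in names(sequences)) {
    al <- global_align(reference, sequences[[nm]])
    if (al$pident < min_identity) {
      warning(sprintf("sequence '%s' excluded: %.1f%% identity to reference",
                      nm, al$pident))
      next
    }
    a <- strsplit(al$aligned_a, "")[[1]]
    b <- strsplit(al$aligned_b, "")[[1]]
    sub <- rep("-", L)
    ins <- rep("", L + 1L)  # ins[p + 1] = insertion after reference pos p
    p <- 0L
    for (k in seq_along(a)) {
      if (a[k] != "-") {
        p <- p + 1L
        sub[p] <- b[k]
      } else {
        ins[p + 1L] <- paste0(ins[p + 1L], b[k])
      }
    }
    subs[[nm]] <- sub; inss[[nm]] <- ins
  }
  if (length(subs) == 0) stop("no sequences alignable to the reference")
  ins_len <- vapply(seq_len(L + 1L), function(p)
    max(vapply(inss, function(x) nchar(x[p]), 0L)), 0L)
  taxa <- names(subs)
  ncols <- L + sum(ins_len)
  build_row <- function(sub, ins) {
    out <- character(0)
    for (p in 0:L) {
      if (p > 0) out <- c(out, sub[p])
      if (ins_len[p + 1L] > 0) {
        x <- strsplit(ins[p + 1L], "")[[1]]
        out <- c(out, x, rep("-", ins_len[p + 1L] - length(x)))
      }
    }
    out
  }
  rows <- lapply(taxa, function(nm) build_row(subs[[nm]], inss[[nm]]))
  if (!is.null(ref_label)) {
    refsub <- strsplit(reference, "")[[1]]
    rows <- c(list(build_row(refsub, rep("", L + 1L))), rows)
    taxa <- c(ref_label, taxa)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- taxa
  stopifnot(ncol(m) == ncols)
  m
}

#' Jukes-Cantor distance matrix
#'
#' Pairwise-deletion JC69 distances: for each pair, columns with a gap or N
#' in either member are skipped; with mismatch fraction p, the distance is
#' `-3/4 * log(1 - 4p/3)` substitutions per site. Saturated pairs
#' (p >= 0.75) are capped at `max_distance` with a warning.
#'
#' @param alignment character matrix from [anchored_msa()] (or any rows x
#'   columns single-character matrix).
#' @param max_distance cap for saturated pairs.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
jc_distance <- function(alignment, max_distance = 5) {
  stopifnot(is.matrix(alignment), nrow(alignment) >= 2)
  n <- nrow(alignment)
  taxa <- rownames(alignment)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- alignment[i, ] != "-" & alignment[j, ] != "-" &
        alignment[i, ] != "N" & alignment[j, ] != "N"
      if (!any(ok)) stop("no pairwise-complete columns for taxa ",
                         taxa[i], " / ", taxa[j])
      p <- mean(alignment[i, ok] != alignment[j, ok])
      if (p >= 0.75) {
        warning(sprintf("saturated pair %s/%s (p = %.3f): distance capped",
                        taxa[i], taxa[j], p))
        dij <- max_distance
      } else {
        dij <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor joining
#'
#' Standard Saitou-Nei agglomeration on a distance matrix, with a
#' deterministic tie-break (tied Q values resolved by the alphabetical
#' order of the smallest leaf label in each candidate cluster). Additive
#' matrices are reconstructed exactly; negative branch-length estimates are
#' clamped to zero. Returns an unrooted `ape::phylo` tree.
#'
#' @param dm symmetric distance matrix with row/column names (>= 3 taxa).
#' @return an `ape::phylo` object.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining requires at least 3 taxa")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
  labs <- rownames(dm)
  nwk <- labs          # newick fragment per active node
  minleaf <- labs      # smallest contained leaf label, for tie-breaking
  D <- dm
  fmt <- function(x) sprintf("%.12g", max(0, x))
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      pr <- sort(c(minleaf[ij[1]], minleaf[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    node <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
    newleaf <- min(minleaf[i], minleaf[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nwk <- c(nwk[keep], node)
    minleaf <- c(minleaf[keep], newleaf)
    rownames(D) <- colnames(D) <- NULL
  }
  # final three-point join
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(v1), nwk[2], fmt(v2),
                 nwk[3], fmt(v3))
  ape::read.tree(text = txt)
}

# tip labels under each node of a phylo (rooted at ape's root)
node_tips <- function(tree) {
  nt <- length(tree$tip.label)
  res <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) res[[i]] <- tree$tip.label[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    res[[p]] <- c(res[[p]], res[[ch]])
  }
  res
}

# canonical split key for a set of tips: the side not containing the
# alphabetically first tip, sorted and collapsed
split_key <- function(side, all_tips) {
  ref <- sort(all_tips)[1]
  if (ref %in% side) side <- setdiff(all_tips, side)
  if (length(side) == 0) return(NA_character_)
  paste(sort(side), collapse = "|")
}

# keys of all non-trivial (internal-edge) splits of a tree
tree_splits <- function(tree) {
  nt <- length(tree$tip.label)
  tips <- node_tips(tree)
  all_tips <- tree$tip.label
  internal <- tree$edge[tree$edge[, 2] > nt, 2]
  keys <- vapply(internal, function(nd) split_key(tips[[nd]], all_tips), "")
  keys[!is.na(keys) & vapply(internal, function(nd) {
    k <- length(tips[[nd]]); k >= 2 && k <= nt - 2
  }, TRUE)]
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the JC69 + NJ
#' tree per replicate, and maps the frequency of each internal split of the
#' full-data tree onto its node labels (0-100). Supports on zero-length
#' branches are flagged NA (they are undefined when sequences are
#' identical).
#'
#' @param alignment character matrix (>= 4 columns).
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @param max_distance passed to [jc_distance()].
#' @return the full-data `phylo` tree with `node.label` supports.
#' @export
nj_bootstrap <- function(alignment, n_reps = 1000L, seed = 1L,
                         max_distance = 5) {
  stopifnot(ncol(alignment) >= 4)
  set.seed(seed)
  full <- neighbor_joining(jc_distance(alignment, max_distance))
  nt <- length(full$tip.label)
  tips <- node_tips(full)
  all_tips <- full$tip.label
  node_key <- rep(NA_character_, full$Nnode)
  for (nd in (nt + 1):(nt + full$Nnode)) {
    k <- length(tips[[nd]])
    if (k >= 2 && k <= nt - 2) node_key[nd - nt] <- split_key(tips[[nd]], all_tips)
  }
  counts <- setNames(rep(0L, sum(!is.na(node_key))),
                     node_key[!is.na(node_key)])
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(alignment), ncol(alignment), replace = TRUE)
    rep_tree <- suppressWarnings(
      neighbor_joining(jc_distance(alignment[, cols, drop = FALSE],
                                   max_distance)))
    ks <- tree_splits(rep_tree)
    hit <- names(counts) %in% ks
    counts[hit] <- counts[hit] + 1L
  }
  lab <- rep(NA_character_, full$Nnode)
  # zero-length internal branches carry undefined support
  zero_nodes <- full$edge[full$edge[, 2] > nt & full$edge.length == 0, 2] - nt
  for (nd in seq_len(full$Nnode)) {
    if (!is.na(node_key[nd]) && !(nd %in% zero_nodes)) {
      lab[nd] <- as.character(round(100 * counts[[node_key[nd]]] / n_reps))
    }
  }
  full$node.label <- lab
  full
}

#' Per-species monophyly (independent-origin test)
#'
#' For each species contributing at least two pseudogenes, reports whether
#' its members form a clade on the unrooted tree (a split separating
#' exactly those leaves). All multi-member species monophyletic supports
#' the hypothesis that the copies arose independently per species after
#' speciation; a violation indicates a copy predating the species split.
#' Verdicts are invariant under leaf permutation and re-rooting.
#'
#' @param tree a `phylo` tree.
#' @param species_of named character vector mapping every leaf label to a
#'   species.
#' @return list: `per_species` data frame (`species`, `n`, `monophyletic`)
#'   and `all_monophyletic`.
#' @export
independent_origin_test <- function(tree, species_of) {
  leaves <- tree$tip.label
  missing <- setdiff(leaves, names(species_of))
  if (length(missing) > 0)
    stop("species map missing leaves: ", paste(missing, collapse = ", "))
  keys <- tree_splits(tree)
  all_tips <- leaves
  species <- unique(unname(species_of[leaves]))
  rows <- lapply(species, function(sp) {
    mem <- leaves[species_of[leaves] == sp]
    mono <- if (length(mem) < 2 || length(mem) >= length(leaves) - 1) TRUE
      else split_key(mem, all_tips) %in% keys
    data.frame(species = sp, n = length(mem), monophyletic = mono,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  list(per_species = df, all_monophyletic = all(df$monophyletic))
}
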
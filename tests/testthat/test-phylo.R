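test_that("anchored alignment projects variation onto reference columns", {
  set.seed(60)
  base <- rand_dna(200)
  same <- setNames(c(base, base, base), c("a", "b", "c"))
  msa <- anchored_msa(same, base)
  expect_equal(sum(apply(msa, 2, function(col) length(unique(col)) > 1)), 0L)

  one <- base
  substr(one, 77, 77) <- setdiff(c("A", "C", "G", "T"), substr(base, 77, 77))[1]
  msa1 <- anchored_msa(c(a = base, b = one), base)
  expect_equal(sum(apply(msa1, 2, function(col) length(unique(col)) > 1)), 1L)

  # pairwise identities read off the alignment match direct global alignment
  seqs <- setNames(vapply(1:5, function(i) mutate_seq(base, 0.04), ""),
                   paste0("t", 1:5))
  msa5 <- anchored_msa(seqs, base)
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- msa5[i, ] != "-" & msa5[j, ] != "-"
    msa_id <- 100 * mean(msa5[i, ok] == msa5[j, ok])
    direct <- global_align(seqs[[i]], seqs[[j]])$pident
    expect_lt(abs(msa_id - direct), 0.5)
  }
  expect_warning(anchored_msa(c(x = rand_dna(200), y = base), base),
                 "excluded")
})

test_that("JC69 distances match the closed form and its limits", {
  mk <- function(p, L = 1000) {
    a <- strsplit(strrep("ACGT", L / 4), "")[[1]]
    b <- a
    idx <- seq_len(round(p * L))
    b[idx] <- c(C = "G", A = "C", G = "T", T = "A")[a[idx]]
    rbind(a = a, b = b)
  }
  expect_equal(jc_distance(mk(0))["a", "b"], 0)
  expect_equal(jc_distance(mk(0.10))["a", "b"],
               -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(jc_distance(mk(0.30))["a", "b"],
               -0.75 * log(1 - 1.2 / 3), tolerance = 1e-9)
  # small-p limit: d/p -> 1
  expect_equal(jc_distance(mk(0.001))["a", "b"] / 0.001, 1, tolerance = 0.01)
  expect_warning(cap <- jc_distance(mk(0.80))["a", "b"], "capped")
  expect_equal(cap, 5)
})

test_that("neighbor joining is exact on additive matrices", {
  # three taxa: the unique topology with three-point branch lengths
  dm3 <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(dm3)
  expect_equal(sort(t3$edge.length), c(2, 3, 5))
  expect_equal(ape::cophenetic.phylo(t3)[c("A", "B", "C"), c("A", "B", "C")],
               dm3)
  # four-taxon additive matrix: true split and exact path lengths
  t4 <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:1):2);")
  dm4 <- ape::cophenetic.phylo(t4)
  nj4 <- neighbor_joining(dm4)
  expect_equal(ape::cophenetic.phylo(nj4)[rownames(dm4), colnames(dm4)], dm4)
  expect_equal(ape::dist.topo(ape::unroot(t4), ape::unroot(nj4)), 0,
               ignore_attr = TRUE)
  # random additive trees up to 10 taxa reconstruct exactly, and agree with
  # the independent ape implementation
  set.seed(61)
  for (i in 1:5) {
    tr <- ape::rtree(sample(4:10, 1))
    dm <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(dm)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(nj),
                                ape::unroot(ape::nj(dm))), 0,
                 ignore_attr = TRUE)
  }
  expect_error(neighbor_joining(dm3[1:2, 1:2]), "at least 3")
})

test_that("bootstrap supports are deterministic and strong when structure is", {
  set.seed(62)
  base <- rand_dna(600)
  cl1 <- mutate_seq(base, 0.05)
  cl2 <- mutate_seq(base, 0.05)
  seqs <- c(a1 = mutate_seq(cl1, 0.005), a2 = mutate_seq(cl1, 0.005),
            a3 = mutate_seq(cl1, 0.005),
            b1 = mutate_seq(cl2, 0.005), b2 = mutate_seq(cl2, 0.005),
            b3 = mutate_seq(cl2, 0.005))
  msa <- anchored_msa(seqs, base)
  t1 <- nj_bootstrap(msa, n_reps = 200, seed = 9)
  t2 <- nj_bootstrap(msa, n_reps = 200, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  # the deep split between the two 3-member clades is near-certain
  expect_gte(max(sup, na.rm = TRUE), 95)
  # convergence: 500 vs 1000 replicates agree within 5 points per split
  t500 <- nj_bootstrap(msa, n_reps = 500, seed = 10)
  t1000 <- nj_bootstrap(msa, n_reps = 1000, seed = 11)
  s500 <- as.numeric(t500$node.label); s1000 <- as.numeric(t1000$node.label)
  expect_true(all(abs(s500 - s1000) <= 5, na.rm = TRUE))
  expect_error(nj_bootstrap(msa[, 1:3], 10, 1), "ncol")
})

test_that("per-species monophyly separates post- from pre-speciation copies", {
  set.seed(63)
  base <- rand_dna(500)
  gene_sp <- lapply(1:3, function(i) mutate_seq(base, 0.05))
  # post-speciation: every copy derives from its own species' gene
  seqs <- c(); spmap <- c()
  for (i in 1:3) for (k in 1:2) {
    nm <- sprintf("sp%d_p%d", i, k)
    seqs[nm] <- mutate_seq(gene_sp[[i]], 0.005)
    spmap[nm] <- paste0("sp", i)
  }
  tree <- neighbor_joining(jc_distance(anchored_msa(seqs, base)))
  iot <- independent_origin_test(tree, spmap)
  expect_true(iot$all_monophyletic)
  expect_equal(nrow(iot$per_species), 3L)

  # pre-speciation: an ancestral copy inherited by sp1 and sp2
  anc <- mutate_seq(base, 0.04)
  seqs2 <- c(sp1_old = mutate_seq(anc, 0.01), sp2_old = mutate_seq(anc, 0.01),
             sp1_new = mutate_seq(gene_sp[[1]], 0.005),
             sp2_new = mutate_seq(gene_sp[[2]], 0.005))
  spmap2 <- c(sp1_old = "sp1", sp2_old = "sp2",
              sp1_new = "sp1", sp2_new = "sp2")
  tree2 <- neighbor_joining(jc_distance(anchored_msa(seqs2, base)))
  iot2 <- independent_origin_test(tree2, spmap2)
  expect_false(iot2$all_monophyletic)
  expect_false(any(iot2$per_species$monophyletic[iot2$per_species$n >= 2]))

  # verdicts invariant under leaf permutation and re-rooting
  perm <- sample(names(spmap))
  iot_perm <- independent_origin_test(tree, spmap[perm])
  expect_equal(sort(paste(iot_perm$per_species$species,
                          iot_perm$per_species$monophyletic)),
               sort(paste(iot$per_species$species,
                          iot$per_species$monophyletic)))
  rooted <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  iot_root <- independent_origin_test(rooted, spmap)
  expect_equal(iot_root$all_monophyletic, iot$all_monophyletic)

  expect_error(independent_origin_test(tree, spmap[-1]), "missing")
})

test_that("a simulated multi-species census recovers species clades", {
  # 13 pseudogenes from 7 species, within-species divergence below
  # between-species divergence
  set.seed(64)
  base <- rand_dna(400)
  n_per <- c(1, 1, 4, 1, 2, 1, 3)  # 13 copies over 7 species
  seqs <- c(); spmap <- c()
  for (s in seq_along(n_per)) {
    g <- mutate_seq(base, 0.06)
    for (k in seq_len(n_per[s])) {
      nm <- sprintf("sp%d_p%d", s, k)
      seqs[nm] <- mutate_seq(g, 0.004)
      spmap[nm] <- paste0("sp", s)
    }
  }
  tree <- neighbor_joining(jc_distance(anchored_msa(seqs, base)))
  iot <- independent_origin_test(tree, spmap)
  expect_true(iot$all_monophyletic)
  expect_equal(sum(iot$per_species$n), 13L)
})
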
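test_that("longest ORF finding: toy case, planted CDS, premature stop", {
  orf <- longest_orf("ATGAAATAA", min_codons = 1)
  expect_equal(orf$codons, 2L)
  expect_identical(orf$protein, "MK")

  # an undamaged 199-codon CDS embedded in UTRs
  cfg <- small_cfg(seed = 50, n_retrocopies = 0)
  sim <- simulate_locus(cfg)
  orf2 <- longest_orf(sim$truth$gene$mrna)
  expect_equal(orf2$codons, 199L)
  expect_identical(orf2$protein, authentic_protein_of(sim$truth, cfg))

  # premature stop at codon 124 truncates the frame to 123 codons
  cds <- paste0("ATG", strrep("GCT", 198), "TAA")
  damaged <- cds
  substr(damaged, 3 * 123 + 1, 3 * 124) <- "TAA"
  expect_equal(longest_orf(damaged)$codons, 123L)

  # nothing above the reporting threshold
  expect_equal(longest_orf(paste0("ATG", strrep("GCT", 10), "TAA"))$codons, 0L)
  expect_equal(longest_orf(strrep("GCT", 100))$codons, 0L)
})

test_that("protein reports reproduce published identity/substitution pairs", {
  set.seed(51)
  p <- rand_protein(199)
  expect_equal(protein_report(p, p)$pident, 100)
  expect_length(protein_report(p, p)$substitutions, 0L)

  # single D180 > E style change: 99.5% with the notation recorded
  auth <- apply_subs(p, 180, "D")
  pred <- apply_subs(auth, 180, "E")
  r1 <- protein_report(pred, auth)
  expect_equal(r1$pident, 99.5)
  expect_identical(r1$substitutions, "D180>E")

  # two substitutions: 99.0% with both listed
  auth2 <- apply_subs(p, c(170, 176), c("R", "T"))
  pred2 <- apply_subs(auth2, c(170, 176), c("K", "A"))
  r2 <- protein_report(pred2, auth2)
  expect_equal(r2$pident, 99.0)
  expect_setequal(r2$substitutions, c("R170>K", "T176>A"))

  # a 123-codon ORF with one change against the full protein: 99.2%
  pred3 <- apply_subs(substr(auth, 1, 123), 60)
  expect_equal(protein_report(pred3, auth)$pident, 99.2)
})

test_that("substitution counts track identity for equal-length pairs", {
  set.seed(52)
  p <- rand_protein(199)
  for (k in c(1, 5, 14, 40)) {
    q <- apply_subs(p, sample(199, k))
    r <- protein_report(q, p)
    expect_equal(r$n_substitutions, k)
    expect_equal(r$n_substitutions, round(199 * (1 - r$pident / 100)),
                 tolerance = 1)
  }
})

test_that("candidate classification distinguishes the contiguity classes", {
  ref_cfg <- small_cfg(seed = 53, n_retrocopies = 1, retro_divergence = 0.05)
  sim <- simulate_locus(ref_cfg)
  ref <- ref_model_of(sim, ref_cfg)
  auth <- authentic_protein_of(sim$truth, ref_cfg)
  ch <- chain_hits(search_exons(sim, ref_cfg), ref, sim$genome$seq)
  rec <- classify_candidate(ch$clusters[[1]], ref, sim$genome$seq,
                            accepted_models = ch$models,
                            authentic_protein = auth)
  expect_identical(rec$contiguity, "full_length")
  expect_equal(rec$exons_present, 1:6)

  # exons 4-6 only: partial
  cfgp <- small_cfg(seed = 54, n_retrocopies = 1, retro_divergence = 0.05,
                    retro_truncation = 4:6)
  simp <- simulate_locus(cfgp)
  refp <- ref_model_of(simp, cfgp)
  chp <- chain_hits(search_exons(simp, cfgp), refp, simp$genome$seq)
  recp <- classify_candidate(chp$clusters[[1]], refp, simp$genome$seq)
  expect_identical(recp$contiguity, "partial")
  expect_equal(recp$exons_present, 4:6)

  # an unreadable 406-nt N-run between exons 2 and 3: gapped
  cfgg <- small_cfg(seed = 55, n_retrocopies = 1, retro_divergence = 0.05,
                    retro_n_gap = c(2L, 406L))
  simg <- simulate_locus(cfgg)
  refg <- ref_model_of(simg, cfgg)
  chg <- chain_hits(search_exons(simg, cfgg), refg, simg$genome$seq)
  recg <- classify_candidate(chg$clusters[[1]], refg, simg$genome$seq)
  expect_identical(recg$contiguity, "gapped")
  expect_identical(recg$gap_kind, "n_run")

  # a readable foreign insertion between exons 3 and 4: gapped (insertion)
  cfgi <- small_cfg(seed = 59, n_retrocopies = 1, retro_divergence = 0.05,
                    retro_insert = c(3L, 300L))
  simi <- simulate_locus(cfgi)
  refi <- ref_model_of(simi, cfgi)
  chi <- chain_hits(search_exons(simi, cfgi), refi, simi$genome$seq)
  reci <- classify_candidate(chi$clusters[[1]], refi, simi$genome$seq)
  expect_identical(reci$contiguity, "gapped")
  expect_identical(reci$gap_kind, "insertion")

  # exons on different sequences: fragmented
  cl1 <- ch$clusters[[1]][ch$clusters[[1]]$exon == 2, ]
  cl2 <- transform(ch$clusters[[1]][ch$clusters[[1]]$exon == 3, ],
                   subject_id = "other_contig")
  recf <- classify_candidate(list(cl1, cl2), ref,
                             setNames(rep(sim$genome$seq, 2),
                                      c(sim$genome$id, "other_contig")))
  expect_identical(recf$contiguity, "fragmented")

  # overlap with an accepted gene model is rejected with a reason
  gene_hits <- search_exons(sim, ref_cfg)
  gene_cluster <- gene_hits[gene_hits$s_start >= sim$truth$gene$tss &
                              gene_hits$s_end <= sim$truth$gene$cleavage, ]
  recr <- classify_candidate(gene_cluster, ref, sim$genome$seq,
                             accepted_models = ch$models)
  expect_identical(recr$status, "rejected")
  expect_match(recr$reason, "overlaps")
})

test_that("retrocopies are detected with matching contiguity over 20 seeds", {
  for (seed in 1:20) {
    div <- c(0, 0.05, 0.10, 0.15)[(seed %% 4) + 1]
    trunc <- if (seed %% 5 == 0) 4:6 else NULL
    gap <- if (seed %% 7 == 0) c(2L, 150L) else NULL
    cfg <- small_cfg(seed = 300 + seed, n_retrocopies = 1,
                     retro_divergence = div, retro_truncation = trunc,
                     retro_n_gap = gap)
    sim <- simulate_locus(cfg)
    ref <- ref_model_of(sim, cfg)
    ch <- chain_hits(search_exons(sim, cfg), ref, sim$genome$seq)
    expect_length(ch$clusters, 1L)
    rec <- classify_candidate(ch$clusters[[1]], ref, sim$genome$seq,
                              accepted_models = ch$models)
    truth_class <- if (!is.null(gap) && is.null(trunc)) "gapped"
      else if (!is.null(trunc)) "partial" else "full_length"
    expect_identical(rec$contiguity, truth_class)
    tr <- sim$truth$retrocopies[[1]]
    # exact exon composition is guaranteed up to 10% divergence; at 15% an
    # 11-mer seed can be lost, so only the copy-level class is asserted
    if (div <= 0.10) {
      expect_equal(rec$exons_present, tr$exons)
      expect_lte(abs(rec$start - tr$start), 10)
      expect_lte(abs(rec$end - tr$end), 10)
    } else {
      # at 15% divergence at most one exon may lose its seed
      expect_gte(length(intersect(rec$exons_present, tr$exons)),
                 length(tr$exons) - 1L)
    }
  }
})

test_that("discriminating probe pairs differ at exactly one position", {
  set.seed(56)
  a <- rand_dna(300)
  b <- a
  substr(b, 150, 150) <- setdiff(c("A", "C", "G", "T"), substr(a, 150, 150))[1]
  pr <- make_discriminating_probes(a, b)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$offset, 30L)
  expect_equal(pr$pos_a, 150L)
  da <- strsplit(pr$probe_a, "")[[1]]
  db <- strsplit(pr$probe_b, "")[[1]]
  expect_equal(sum(da != db), 1L)
  expect_equal(which(da != db), pr$offset)
  expect_warning(none <- make_discriminating_probes(a, a), "identical")
  expect_equal(nrow(none), 0L)
})

test_that("expression testing uses positive-control logic", {
  # reads from the authentic transcript only: candidate not expressed
  cfg <- small_cfg(seed = 57, n_retrocopies = 1, retro_divergence = 0.01,
                   coverage = 40, error_rate = 0)
  sim <- simulate_locus(cfg)
  reads <- simulate_reads(sim$truth, cfg)
  candidate <- sim$truth$retrocopies[[1]]$seq
  et <- expression_test(sim$truth$gene$mrna, candidate, reads)
  expect_identical(et$expressed, "no")
  expect_gt(et$authentic_count, 0)
  expect_equal(et$candidate_count, 0L)

  # both tandem genes expressed at 3:1 -- both detected, counts ordered
  cfg2 <- small_cfg(seed = 58, duplicate = TRUE, n_retrocopies = 0,
                    duplicate_divergence = 0.01,
                    duplicate_expression = 1 / 3, coverage = 60,
                    error_rate = 0)
  sim2 <- simulate_locus(cfg2)
  reads2 <- simulate_reads(sim2$truth, cfg2)
  et2 <- expression_test(sim2$truth$gene$mrna, sim2$truth$duplicate$mrna,
                         reads2)
  expect_identical(et2$expressed, "yes")
  expect_gt(et2$authentic_count, et2$candidate_count)
  expect_gt(et2$candidate_count, 0)

  # empty library: untestable
  et3 <- expression_test(sim$truth$gene$mrna, candidate, reads[0, ])
  expect_identical(et3$expressed, "untestable")
})

test_that("census applies the full-length rule and handles edge cases", {
  tbl <- zmat2_pseudogene_table()
  cz <- census(tbl)
  expect_equal(sum(cz$table$full_length), 13L)
  expect_equal(length(unique(cz$table$species[cz$table$full_length])), 7L)
  # the N-run-gapped rabbit copy is excluded; the insertion-split marmoset
  # copy is not
  expect_false(any(cz$table$full_length[cz$table$species == "rabbit"]))
  expect_true(all(cz$table$full_length[cz$table$species == "marmoset"]))

  empty <- census(list())
  expect_equal(nrow(empty$table), 0L)
  expect_length(empty$full_length, 0L)

  partial_only <- tbl[tbl$contiguity == "partial", ]
  expect_length(census(partial_only)$full_length, 0L)
})
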
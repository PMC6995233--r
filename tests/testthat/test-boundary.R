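test_that("probe tiles are adjacent 60-mers labeled outward from the anchor", {
  set.seed(40)
  g <- rand_dna(2000)
  t5 <- tile_probes(g, anchor = 1000, side = "five_prime", n_tiles = 5)
  expect_identical(t5$label, letters[1:5])
  expect_equal(t5$end[1], 1000)
  expect_equal(min(t5$start), 1000 - 300 + 1)  # a-e span 300 nt
  expect_true(all(t5$end - t5$start + 1 == 60))
  expect_true(all(diff(t5$start) == -60))      # adjacent, non-overlapping

  t3 <- tile_probes(g, anchor = 500, side = "three_prime", n_tiles = 6)
  expect_identical(t3$label, letters[1:6])
  expect_equal(t3$start[1], 500)
  expect_equal(max(t3$end), 500 + 360 - 1)

  expect_warning(t0 <- tile_probes(g, anchor = 1, side = "five_prime",
                                   n_tiles = 3), "dropped")
  expect_equal(nrow(t0), 0L)
  expect_warning(tile_probes(g, anchor = 1990, side = "three_prime",
                             n_tiles = 2), "dropped")
})

test_that("read support counting tolerates errors and rejects intron reads", {
  cfg <- small_cfg(seed = 41, error_rate = 0, n_retrocopies = 0)
  sim <- simulate_locus(cfg)
  tr <- sim$truth
  tiles <- tile_probes(sim$genome$seq, anchor = tr$gene$exon_end[6] - 180,
                       side = "three_prime", n_tiles = 3)
  probe <- tiles[1, ]
  exact <- data.frame(id = "r1", seq = probe$seq, qual = strrep("I", 60))
  expect_equal(count_support(exact, probe), 1L)
  # two errors in a 60-nt overlap: 58/60 = 96.7% >= 90%, still counted
  err <- probe$seq
  substr(err, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(err, 10, 10))[1]
  substr(err, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(err, 40, 40))[1]
  expect_equal(count_support(data.frame(seq = err), probe), 1L)
  # a read from an intron shares no seed with the probe
  intron_read <- substr(sim$genome$seq, tr$gene$exon_end[1] + 50,
                        tr$gene$exon_end[1] + 124)
  expect_equal(count_support(data.frame(seq = intron_read), probe), 0L)
})

test_that("support counts are monotone non-increasing in the identity threshold", {
  cfg <- small_cfg(seed = 42, error_rate = 0.02, coverage = 15,
                   n_retrocopies = 0)
  sim <- simulate_locus(cfg)
  reads <- simulate_reads(sim$truth, cfg)
  tiles <- tile_probes(sim$genome$seq,
                       anchor = sim$truth$gene$exon_end[6] - 300,
                       side = "three_prime", n_tiles = 2)
  counts <- vapply(c(80, 90, 95, 100), function(thr)
    count_support(reads, tiles[1, ], min_identity = thr), 0L)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("poly-A signal scanning orders hits by proximity", {
  set.seed(43)
  seq1 <- paste0(rand_dna(100), "AATAAA", rand_dna(7))
  seq1 <- gsub("AATAA[AT]", "ACTCCT", substr(seq1, 1, 100)) |>
    paste0("AATAAA", substr(seq1, 107, 113))
  sig <- scan_polyA(seq1, cleavage = nchar(seq1))
  expect_equal(sig$motif[1], "AATAAA")
  expect_equal(sig$distance[1], 7)
  # no signal
  expect_equal(nrow(scan_polyA(strrep("GC", 60), cleavage = 120)), 0L)
  # a closer non-canonical signal ranks first by proximity
  seq2 <- paste0(strrep("C", 60), "AATAAA", strrep("C", 10), "AATAAT",
                 strrep("C", 4))
  sig2 <- scan_polyA(seq2, cleavage = nchar(seq2))
  expect_identical(sig2$motif[1], "AATAAT")
  expect_identical(sig2$motif[2], "AATAAA")
  expect_true(sig2$distance[1] < sig2$distance[2])
})

test_that("promoter scanning finds consensus motifs at the expected rate", {
  set.seed(44)
  hit <- scan_promoter(paste0(strrep("C", 50), "TATATAA", strrep("C", 50)),
                       pos = 100, window = 100)
  expect_true("TATA" %in% hit$motif_class)
  expect_equal(nrow(scan_promoter(strrep("GC", 100), pos = 150)), 0L)
  # frequency on random sequence matches the motif-probability oracle:
  # P(TATAWAW at a position) = (1/4)^5 * (1/2)^2 = 1/4096
  # P(>=1 match in a 100-nt window) = 1 - (1 - 1/4096)^(100-6)
  n_trials <- 600
  hits <- 0L
  for (i in seq_len(n_trials)) {
    s <- rand_dna(106)
    sc <- scan_promoter(s, pos = 107, window = 106)
    if (any(sc$motif_class == "TATA")) hits <- hits + 1L
  }
  p <- 1 - (1 - 1 / 4096)^94
  expect_lt(abs(hits - n_trials * p), 4 * sqrt(n_trials * p * (1 - p)) + 1)
})

test_that("3' ends are recovered within 1 nt and 5' calls never overshoot", {
  hits3 <- 0L
  for (seed in 1:20) {
    cfg <- small_cfg(seed = 200 + seed, coverage = 20, error_rate = 0.01,
                     n_retrocopies = 0)
    sim <- simulate_locus(cfg)
    reads <- simulate_reads(sim$truth, cfg)
    tr <- sim$truth
    bc3 <- call_end(sim$genome, reads, anchor = tr$gene$exon_end[6] - 180,
                    side = "three_prime")
    if (!is.na(bc3$coordinate) &&
        abs(bc3$coordinate - tr$gene$cleavage) <= 1) hits3 <- hits3 + 1L
    if (bc3$evidence == "polyA-junction" &&
        bc3$coordinate == tr$gene$cleavage) {
      expect_equal(bc3$polyA$distance, cfg$polyA_signal_offset)
    }
    bc5 <- call_end(sim$genome, reads, anchor = tr$gene$exon_end[1],
                    side = "five_prime", n_tiles = 3)
    expect_gte(bc5$coordinate, tr$gene$tss)  # reads cannot precede the TSS
  }
  expect_gte(hits3, 19L)  # >= 95% over the batch, allowing one failure
})

test_that("zero-coverage libraries produce an explicit no-call", {
  cfg <- small_cfg(seed = 45, coverage = 0, n_retrocopies = 0)
  sim <- simulate_locus(cfg)
  reads <- simulate_reads(sim$truth, cfg)
  bc <- call_end(sim$genome, reads,
                 anchor = sim$truth$gene$exon_end[6] - 180,
                 side = "three_prime")
  expect_identical(bc$status, "no_call")
  expect_true(is.na(bc$coordinate))
})

test_that("sparse 5' evidence still yields a call flagged tentative", {
  cfg <- small_cfg(seed = 46, coverage = 25, error_rate = 0,
                   five_prime_low_coverage = TRUE, n_retrocopies = 0)
  sim <- simulate_locus(cfg)
  reads <- simulate_reads(sim$truth, cfg)
  bc <- call_end(sim$genome, reads, anchor = sim$truth$gene$tss + 59L,
                 side = "five_prime", n_tiles = 3)
  expect_identical(bc$status, "called")
  expect_identical(bc$confidence, "tentative")
  expect_lte(max(bc$profile$count), 2L)
  expect_gte(bc$coordinate, sim$truth$gene$tss)
})
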
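---
title: "Methods: gene reconstruction, transcript-end mapping and the pseudogene census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene reconstruction, transcript-end mapping and the pseudogene census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the procedures,
the assumptions behind them, the defaults and why they were chosen, and
what the synthetic-data validation does and does not establish.

## The problem

A conserved multi-exon gene — the working template is a mouse-like 6-exon
gene with exon lengths 96/94/124/74/146/1774 nt, introns
337/650/872/388/1234 nt, and a 600-nt coding region (a 199-residue protein
plus stop) beginning 18 nt before the end of exon 1 and ending 144 nt into
exon 6 — is to be characterized in a genome where annotation is absent or
unreliable. Four questions follow: where are the exons and are there tandem
duplicates; where do transcripts actually start and end; which related
sequences are processed pseudogenes (retrocopies) and of what kind; and did
those retrocopies arise before or after the speciation events that separate
the genomes carrying them.

## The synthetic locus generator

`simulate_locus()` plants all of the structures the analysis must recover,
with a single integer seed driving every draw.

* **Background**: i.i.d. uniform A/C/G/T. At the genome sizes used
  (default 40 kb) a uniform background essentially never produces a
  spurious 11-mer seed chain that out-scores a true feature, so planted
  truth is unambiguous.
* **Gene**: exons and introns at the configured lengths; introns carry
  GT..AG terminal dinucleotides (reported by the builder as a QC flag, not
  used as evidence); the coding region is a real ORF (ATG, sense codons,
  single stop).
* **Poly-A signal**: an AATAAA planted so that its last base lies
  `polyA_signal_offset` nt (default 7, the distance observed at the mouse
  locus) upstream of the cleavage site; the 50-nt window upstream of the
  cleavage site is scrubbed of competing AATAAA/AATAAT hexamers so the
  planted signal is the proximal one.
* **Identifiability guards**: the genomic base immediately after the
  cleavage site is forced to be non-A (otherwise no method could place a
  poly-A junction exactly — tail A's and genomic A's are indistinguishable),
  and the 100 nt upstream of the TSS are scrubbed of TATA-box and initiator
  consensus matches, emulating the promoter-less situation observed at the
  real locus. Both are properties of the simulated study conditions, fixed
  at design time.
* **Duplicate**: an optional whole-gene copy, substitution-mutated at
  `duplicate_divergence` (default 0.003, i.e. ~99.7% identity, the observed
  tandem-duplicate regime), reverse-complemented and placed immediately
  upstream so the two exon-1 5' ends face each other (configurable
  overlap, default 0). Its transcript is expressed at
  `duplicate_expression` (default 1/3) of the main gene.
* **Retrocopies**: intronless concatenations of the (optionally truncated)
  exon sequences, substitution-mutated at `retro_divergence` (default 0.10,
  the middle of the 80–95% identity range reported for real copies),
  inserted at non-overlapping positions on random strands. Optional
  interruptions model the two observed pathologies: `retro_n_gap` inserts
  an unreadable N-run (the ~406-nt unreadable block case) and
  `retro_insert` a readable foreign segment (the mobile-element case).
  Mutations are substitutions only; indels are deliberately out of the
  default model because the real copies were analyzed as
  substitution-diverged, and the gap cases are modeled explicitly instead.
* **Reads**: single-end reads sampled uniformly along the mature mRNA plus
  a non-genomic poly-A tail (default 30 nt), so reads crossing the cleavage
  site carry tail sequence and no read precedes the TSS. Counts are
  Poisson with mean `coverage × mRNA length / read length`; errors are
  i.i.d. substitutions (default 0.5%). A `five_prime_low_coverage` mode
  keeps only the two 5'-outermost reads over the first 100 transcript nt,
  reproducing the sparse-5'-evidence regime seen in real libraries.

What the generator does **not** emulate: splice isoforms, paired-end
reads, platform-specific error profiles, indel divergence, target-site
duplications or any specific retro-transposition mechanism (truncation is a
free parameter, not a mechanistic claim), and non-uniform genomic
composition. Passing the recovery tests therefore demonstrates correctness
of the algorithms under clean statistical conditions, not robustness to
every artifact of real data.

## Alignment

`local_search()` is a seed-and-extend local aligner: exact shared words
(default word size 11) are grouped into diagonal bands, and each band is
extended by full affine-gap Smith–Waterman dynamic programming over a
subject window covering the band plus a 100-nt margin. Because the window
always contains the optimal local alignment when a seed exists, the
reported top score equals the full Smith–Waterman score — a property the
test suite checks against an independent dynamic-programming oracle. Two
scoring presets mirror the standard nucleotide-search parameterizations:
`blastn_normal` (+1/−3, gap open 5, extend 2) for cross-species genome
search and `megablast` (+2/−3, same gaps) for near-identical read-vs-probe
queries. A gap of length L costs open + L·extend.

Decisions of note:

* No E-value machinery; a raw minimum score (`min_score`, default 40 for
  megablast and 20 for blastn_normal) stands in for an E-value cutoff.
  Thresholding behavior is preserved and the knob is explicit.
* The word size for the normal-sensitivity preset is not dictated by the
  published search settings (only the megablast word size is); 11 is used
  for both and is configurable.
* A DUST-like low-complexity filter (64-nt windows over triplet
  composition) masks the query before seeding, on by default for search
  and off for global alignment.
* Minus-strand hits are computed on the reverse-complemented query and
  reported in forward subject coordinates.
* Hits are sorted by score then subject start; hits nested inside a
  better hit are merged away. Traceback tie-breaks are fixed
  (match/mismatch, then gap in the first sequence, then the second), so
  results are deterministic.

`global_align()` is Needleman–Wunsch with affine gaps (DNA defaults +2/−3,
5/2; protein defaults +2/−1, 10/1 — identity-oriented scoring, since every
downstream use is an identity or substitution report). Percent identity is
always matches / aligned columns with terminal gap columns excluded,
rounded half away from zero to one decimal; that convention makes a
123-residue ORF with one change against a 199-residue protein come out at
99.2, and 185/199 at 93.0, matching the published tables' arithmetic.

## Gene building

`chain_hits()` groups exon-labeled hits by subject and strand, splits
clusters where the locus gap exceeds `max_intron` (50 kb) or the exon
order resets, and promotes to gene models only clusters whose exons are
colinear with all gaps in [`min_intron`, `max_intron`]. The 50-nt
`min_intron` doubles as the processed/genic discriminator: clusters whose
inter-exon gaps are all below it are intronless retrocopy candidates and
are handed to the pseudogene stage. Gaps that are mostly N are never
counted as introns. Competing overlapping chains are resolved by exon
count, then summed score, then leftmost position. Splice-site
dinucleotides are checked and reported (`splice_qc`) but never enforced —
the reconstruction rests on homology and colinearity alone.

On simulated loci the builder recovers exon boundaries exactly at zero
divergence. At non-zero divergence, local alignment necessarily trims
mutated terminal bases (a terminal mismatch can never end an optimal local
alignment), so boundaries are recovered within a couple of nucleotides at
the ~0.3% divergence of a tandem duplicate — the resolution limit of
homology evidence, not an implementation artifact.

## Transcript-end mapping

Probes are adjacent, non-overlapping 60-mers tiled outward from an anchor
inside the transcript (adjacency is the plain reading of the published
probe diagrams, which letter the segments a, b, c, ... without stating an
overlap; the number of tiles per side is a knob, default 6). A read
supports a probe when its best local alignment covers at least 50 of the
60 probe positions at ≥ 90% identity — a criterion chosen to tolerate
roughly one sequencing error per probe-length segment while excluding
paralogous background.

The 3' caller prefers direct junction evidence: reads with at least 8
trailing A's (8 distinguishes real tails from chance genomic A-runs, and
is configurable) are tail-trimmed, their bodies aligned to the region, and
trailing A's that continue the genome are re-assigned as genomic before
requiring 8 non-genomic tail bases. The cleavage site is the modal
junction; the nearest upstream AATAAA/AATAAT within 50 nt is reported with
its distance, canonical motif first at equal distance. Without junction
reads the caller falls back to the outermost aligned base of reads
supporting the outermost supported tile and labels the call `tentative`.
The 5' side always uses that longest-clone rule, and is `tentative` unless
a TATA (TATAWAW) or initiator (YYANWYY) consensus lies within 100 nt
upstream. An all-zero profile produces an explicit no-call, mirroring
species where no expressing library exists.

## Pseudogene census

`classify_candidate()` assigns exon composition and a contiguity class:

* `fragmented` — exons on different sequences;
* `gapped` — the exon run is interrupted, with `gap_kind` separating
  unreadable N-runs from readable foreign insertions;
* `partial` — a proper exon subset;
* `full_length` — all exons in one contiguous intronless run.

Readable gaps need care. At 10–15% divergence an exon can lose every exact
11-mer seed, leaving a readable "gap" that is actually diverged exon
sequence, and alignment edges fray by a few bases. So a readable gap
counts as an insertion only when it is at least 100 nt **and** fails a
transcript-likeness test (best local alignment of the gap sequence to the
reference mRNA scoring below 0.5 per base); a transcript-like spacer
instead rescues any exon indices it skips. This keeps the marmoset-style
mobile-element split detectable while not degrading high-divergence copies.

The census' full-length rule is: all reference exons present at a single
locus, not fragmented, no unreadable N-run. A readable insertion does not
demote an otherwise complete copy — the copy's own sequence is all present
and readable. Applied to the packaged records this rule yields exactly the
published count of 13 full-length pseudogenes from 7 species: the
N-run-interrupted rabbit copy falls out, the element-split marmoset copy
stays in. (Counting the marmoset copy out would give 12; the published
count is only consistent with the rule stated here, which is why it is the
operative definition.)

ORF finding scans both strands (a retrocopy inserts in either orientation)
for the longest ATG-initiated, stop-terminated frame, reporting codons
excluding the stop; anything under 30 codons reports as none (the smallest
published ORF in the census is 90 codons, so the threshold is conservative
and configurable). Protein reports use the global aligner and emit
substitutions as `X<pos>>Y` with positions on the authentic protein.

Expression testing is deliberately exact: discriminating probes are
60-mers centered on isolated single-nucleotide differences (emitted only
where the window contains no other difference, so each pair differs at
exactly one position), and reads are counted by exact substring match in
either orientation — the only matching regime in which single-nucleotide
discrimination is sound. The verdict is `no` only when the authentic-probe
count is positive and the candidate count is zero (positive-control
logic); with no reads or no informative probes the record stays
`untestable`, never `no`.

## Phylogeny

The published analysis used maximum-likelihood tree inference; this
package substitutes neighbor joining on JC69 distances. The conclusion
being tested is purely topological — do copies from the same species form
clades — and NJ recovers that structure under the simulated regimes while
keeping the implementation dependency-free and exactly testable (NJ is
provably exact on additive matrices, and the suite verifies this on random
additive trees). Branch lengths are in substitutions per site via
d = −¾ ln(1 − 4p/3), matching the scale of the published trees; JC69 is
used rather than raw p-distance for that reason. The Newick output carries
bootstrap supports, so users wanting ML parity can feed the same alignment
to an external ML tool.

Details: the reference-anchored MSA projects each pairwise global
alignment onto reference coordinates, merging reference-relative
insertions left-aligned; sequences under 50% identity to the reference are
excluded with a warning. Distances use pairwise deletion (columns with a
gap or N in either member are skipped for that pair); saturated pairs
(p ≥ 0.75) are capped at a configurable maximum (default 5) with a
warning. NJ tie-breaks are deterministic (alphabetical order of the
smallest contained leaf label) and negative branch-length estimates are
clamped to zero. The bootstrap resamples alignment columns with
replacement (default 1000 replicates, the published setting; the test
suite runs 200–1000), maps split frequencies onto the full-data tree, and
flags supports on zero-length branches as undefined. Monophyly of a leaf
set on the unrooted tree means some edge bipartition separates exactly
that set; verdicts are invariant under leaf permutation and re-rooting,
which the suite checks.

## Problem sizes in the test suite

The suite validates every stage on simulated data sized for quick,
repeated runs: the full mouse-like locus (40-kb genome, 2308-nt mRNA) for
the worked examples and the 3'-end acceptance scenario, and a compact
variant with a 400-nt terminal exon (20-kb genome, 934-nt mRNA) for the
20-seed recovery loops; bootstrap tests use 6–13 taxa and 200–1000
replicates. These sizes are the package's choice for its own validation;
every algorithm accepts full-scale inputs.

## Known limitations

* Substitution-only divergence: indel-diverged retrocopies are not
  simulated (though the aligner handles gaps), and the classifier's
  spacer/insertion discrimination assumes the reference transcript is the
  right template.
* Seed-based search loses exons at high divergence with small exons
  (an exact 11-mer must survive); below ~85% identity the per-exon
  detection probability drops noticeably for exons under ~100 nt. The
  spacer-rescue logic recovers skipped internal exons, but terminal exons
  lost this way shorten the reported copy.
* The 3'-end caller assumes a sense-strand read library and single-end
  reads.
* Expression probes require reads at least as long as the probe (default
  60 nt).
* NJ topology, not ML: branch lengths are distance-based estimates and no
  model selection is performed.
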
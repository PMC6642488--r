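---
title: "dgrfinder: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dgrfinder: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why:
the detection model, the tunable parameters and their defaults, what
the synthetic world does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The detection model

A diversity-generating retroelement (DGR) couples three elements: a
template repeat (TR), one or more variable repeats (VR) that are
adenine-mutagenized copies of the TR, and a reverse transcriptase gene
(RT). `dgrfinder` detects TRs and RTs by sequence pattern and VRs by
TR-anchored homology, so no DGR reference collection is consulted at
scan time.

### PWM motif states in a duration-explicit HMM

Each element submodel is an ordered set of PWM motif states with an
explicit inter-motif spacer-length distribution. A placement of a
subset of the motif states (in model order) at offsets
$o_1 < \dots < o_m$ scores the sum of per-window PWM log-odds, log
transition probabilities over `begin`, the motif states and `end`, and
the log probability of each observed spacer length. Decoding maximizes
this score with a duration-explicit Viterbi pass
(`viterbi_decode()`); an empty path is reported as score $-\infty$.

Design choices the field's practice does not fix:

* **Log-odds scoring against a background model.** Only "maximum
  score" decoding is prescribed by the approach this package follows;
  log-odds against the background composition is standard PWM practice
  and makes 0 an interpretable score floor.
* **Skippable motif states.** Paths may omit motif states (with the
  transition penalty estimated from training data); partial motifs
  occur in degraded elements and the training data decides how costly
  skipping is. If training examples never skip, skipping is simply
  impossible under the maximum-likelihood transitions.
* **Tie-breaking.** Equal-scoring placements resolve to the leftmost
  start, then the shortest span. This matters only for degenerate
  (e.g. uniform) models and is covered by a dedicated test.
* **Windowed scanning.** `scan_elements()` slides a window of four
  nominal model spans (step: half a window) over both strands so that
  several elements per contig can be reported even though each Viterbi
  pass returns one best path. Overlapping same-type calls are resolved
  greedily by descending score (ties: leftmost, then lower subgroup
  id) — deterministic, and equivalent to per-locus maximum-score
  selection in all non-pathological cases.

### Training

`train_models()` partitions each element type's training set into
`k = 3` subgroups (average-linkage hierarchical clustering on pairwise
global-alignment identity, the analogue of subdividing a repeat
reference into families), then per subgroup builds PWMs from the
annotated motif windows (Laplace pseudocount 0.5 by default) and
estimates transitions and spacer histograms by maximum likelihood.
Numerical details:

* Transition smoothing is +1 over the successors actually observed for
  each state, keeping rows stochastic without inventing never-observed
  moves.
* Spacer histograms get a floor of $10^{-6}$ across their support, and
  the support is padded by 2 nt on each side (clamped at 0). The pad is
  deliberate: with finite training data the observed spacer range
  underestimates the true range, and a planted spacer one base outside
  the observed range should be penalized, not forbidden.
* Score thresholds are calibrated per submodel on synthetic negative
  sequences at the DGR background composition: the threshold is the
  empirical $1 - 10^{-3}$ quantile of per-2 kb best scores (type-1
  quantile over 200 negatives by default), targeting a false positive
  rate of at most 0.1% per 2 kb per submodel. No thresholds are
  published for the system this reimplements, so calibration on the
  negative protocol is the principled substitute.

### VR search

VRs are found from each TR with two asymmetries that encode the
biology:

* **Adenine-wildcard seeding.** 8-mers of the TR, every 4 nt, with TR
  adenines treated as wildcards. Seeds with fewer than 5 non-A
  positions are skipped (in AAC-rich templates they match everywhere
  and carry no signal), and a candidate locus must collect at least 3
  seed hits on its best diagonal — substitution-only VR copies put all
  seed hits on one diagonal, while random collisions rarely reach
  three. This replaces BLAST seeding and is what retrieves VRs whose
  longest identical segment is below the default BLASTN seed length
  of 11.
* **Adenine-neutral local alignment.** Smith–Waterman with affine gaps
  (match +2, gap open −5, extend −2) in which a mismatch at a
  TR-adenine column costs 0 and any other mismatch −3. Setting the two
  mismatch penalties equal provably collapses the aligner to a
  textbook local aligner (an acceptance criterion). Among equal-scoring
  alignments the longer one is preferred, so fully mutagenized adenine
  runs stay inside the reported footprint.

Retention uses the published thresholds verbatim and strictly:
alignment length > 30 columns, identity > 0.60, non-A-to-N
substitutions < 4. Identity counts identical aligned columns over all
columns (gaps count in the denominator, and A-to-N substitutions count
as mismatches — consistent with a reported pair of ~122 aligned
columns, 90.2% identity and 12 A-to-N substitutions). Whether the
original identity was computed over gapped or ungapped alignments is
unstated; gapped-with-gaps-as-mismatch is this package's recorded
choice. Pairs with zero substitutions (perfect non-self copies) are
retained, since highly repetitive TRs with near-identical copies are a
documented phenomenon. The TR's own locus is excluded by coordinate
overlap.

One consequence of adenine-neutral scoring deserves a flag: a mutated
TR copy usually also scores above the TR model threshold, so the same
locus would be reported as both a TR and a VR. `run_pipeline()`
therefore demotes any TR call that is covered (≥ 50%) by a retained VR
of a strictly higher-scoring TR, and drops the demoted call's mirror
pairs. When two copies are exactly symmetric the higher Viterbi score
decides which one is the template.

### ORFs, cassette assembly, clustering, statistics

* ORFs come from six-frame translation with ATG as the only start
  codon and a minimum coding length of 120 nt (40 aa), read as
  excluding the stop codon (40 aa × 3 = 120). One ORF per stop (the
  first ATG after the previous stop); edge-truncated ORFs are kept
  with `complete = FALSE` because metagenomic contigs truncate genes.
  Each merged VR maps to the longest overlapping ORF regardless of
  strand (VR orientation relative to its target varies across
  cassettes).
* Loci are chained by single linkage with a 20 kb window (no maximum
  element spacing is published; 20 kb comfortably contains every
  reported cassette while keeping unrelated elements apart). A locus
  with TR and RT is a record: `intact` with at least one retained VR,
  `partial` otherwise.
* The cassette signature lists elements left to right with orientation
  and run-length-encoded multiplicity, canonicalized so the
  highest-scoring RT reads forward; a global strand flip of the locus
  therefore never changes the signature. Canonicalizing on the RT
  (rather than on the TR or VR) is this package's recorded choice.
* RT non-redundancy is greedy length-sorted clustering at 90% global
  identity (identity = matches / alignment length, gaps counted),
  mirroring cd-hit's global-identity default but with full alignments
  instead of k-mer shortcuts — correctness over speed at desk scale.
* The substitution spectrum counts gap-free aligned columns; the
  per-pair non-A-to-N frequency uses the gap-free column count as its
  denominator. The chi-square independence test is Pearson's with the
  Yates continuity correction for 2×2 tables (mirroring the default of
  the R test the field uses); the uncorrected statistic is available
  by flag. Raw p-values are reported without multiplicity correction,
  as in the practice this reproduces.
* Read confirmation of partial DGRs: candidate reads share a
  3-supported wildcard-seed diagonal with the TR, read-level VR calls
  pass (non-A-to-N ≤ 3, length > 30, identity > 0.60), and a VR
  footprint is confirmed by ≥ 2 reads grouped by overlap on the TR
  (whether the original requires identical variant patterns per read
  is unstated; footprint grouping is the recorded choice). Coverage is
  reported as `100 × reads / locus length` — the published convention,
  which equals true depth only for ~100 bp reads.

## The synthetic world

`generate_dgr_genome()` implants a cassette with a fixed element
design: a 120 bp TR (two AAC-rich flanking codons, three 12 bp motifs
separated by spacers of 30–42 nt summing to 72, all codon-aligned and
stop-free so the TR can sit inside a target ORF), VR copies embedded at
the 3′ end of generated target ORFs, and an RT ORF carrying four 18 bp
motifs. Motif consensi are a fixed package constant
(`dgr_default_motifs()`): three families per element type, TR motifs
built from one AAC codon plus three adenine-free anchor codons.
Fixtures and models are co-generated from this one motif set, keeping
pipeline tests closed-loop.

Mutation-model defaults encode the reported cohort averages, not any
single DGR:

* adenine substitution rate defaults to `15 / (number of TR adenines)`
  so 15 A-to-N substitutions are expected per VR;
* non-A substitution rate defaults to `1.5 / (number of TR non-A
  positions)` so 1.5 non-A-to-N substitutions are expected per VR.
  The alternative reading — 2.58% per non-A site, from the average
  non-A-to-N *frequency* — is a conditional statistic (computed only
  over pairs that contain such substitutions) and would triple the
  unconditional mean; an independent per-site model cannot match both
  numbers because real pairs are overdispersed, so the unconditional
  mean is the anchor;
* the replacement kernel sends half of replaced adenines to guanine,
  and encodes the reported qualitative biases for the other bases
  (G → A relatively likely, C → A least likely, T preferring C).

What the generator does **not** emulate: indels between TR and VR,
sequencing/assembly error in contigs, chimeric or strain-mixed
assemblies, IMH/IMH* terminal sequences, and accessory genes. A green
implant-recovery test therefore establishes that the pipeline recovers
substitution-type divergence under realistic composition — not that it
tolerates assembly artifacts. Roughly 7% of generated VRs carry ≥ 4
non-A-to-N substitutions by chance and are rejected by the package's
own (published) filter; the ≥ 90% recovery criterion already absorbs
this, and those misses are the filter working as specified, not a
search failure.

The gold-negative generator draws i.i.d. sequences at the DGR
background composition (package default A/T 0.30, C/G 0.20). Tests use
10,000 sequences of 2 kb, scaled down from the 100,000-sequence
protocol; the criterion (≥ 99.5% of negatives free of intact calls) is
unchanged by the scaling.

## Known limitations

* The GHMM allows motif-state skipping only insofar as the training
  data exhibits it; a half-present TR with a novel motif arrangement
  scores poorly.
* Wildcard seeding assumes substitution-dominated TR–VR divergence;
  a VR fragmented by large indels may be missed even though the
  aligner itself handles gaps.
* `partition_training_set()` computes all pairwise global alignments
  (quadratic); it is meant for curated training sets of hundreds of
  examples, not thousands.
* Cross-contig DGRs (elements split over assembly breaks) are not
  stitched; each contig is assembled independently, which is why
  partial records plus read confirmation exist.
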
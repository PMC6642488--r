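# dgrfinder

Detection of diversity-generating retroelements (DGRs) in bacterial
genomes and metagenome assemblies, without alignment against a DGR
reference collection.

## The problem

DGRs are mobile cassettes that hypermutate a target gene. A reverse
transcriptase (RT) copies an invariant **template repeat (TR)** into
cDNA with adenine-specific errors, and the mutagenized copy is written
into a homologous **variable repeat (VR)**, typically at the 3′ end of
the target gene. The telltale signature of an active DGR is therefore a
TR–VR pair whose differences sit almost exclusively at TR-adenine
positions. Because VRs can diverge enormously from their TR (dozens of
replaced adenines, with the longest identical stretch shorter than a
BLAST seed), alignment-based homology search misses exactly the most
interesting cases, and scanning against ever-growing DGR reference sets
scales poorly on metagenomes.

`dgrfinder` takes the pattern-based route:

* **TRs and RTs** are detected by position weight matrices (PWMs)
  embedded as motif states in a generalized (explicit-duration) hidden
  Markov model. For a model with motif states $M_1,\dots,M_K$, a
  candidate placement with offsets $o_1 < \dots < o_m$ scores

  $$S = \sum_i \mathrm{LO}(M_{s_i}, o_i) + \sum_i \log T_{s_{i-1} s_i}
        + \sum_i \log P_{s_{i-1} s_i}(d_i),$$

  where $\mathrm{LO}$ is the PWM log-odds against the background
  composition, $T$ the state-transition matrix, and $P(d)$ the
  empirical spacer-length distribution; the maximizing placement is
  found by a duration-explicit Viterbi pass. Three submodels per
  element type are trained on clustered subgroups of the training set.
* **VRs** are found from each candidate TR by adenine-wildcard k-mer
  seeding (template adenines match any base) followed by a local
  aligner whose mismatch penalty at TR-adenine columns is zero, so a VR
  with every adenine rewritten still aligns end-to-end. Pairs are kept
  when the alignment is longer than 30 columns, identity exceeds 60%,
  and fewer than four non-A-to-N substitutions are present.
* **Cassettes** are assembled per locus (intact = TR + VR + RT;
  partial = TR + RT), classified by a strand-canonical cassette
  signature, made non-redundant by greedy 90%-identity RT clustering,
  and summarized by their substitution spectrum. Partial DGRs can be
  confirmed from raw reads (at least two reads, each with at most three
  non-A-to-N substitutions).
* A **synthetic-genome generator** implants cassettes with a
  parameterized adenine-specific mutation model (defaults: 15 expected
  A-to-N and 1.5 expected non-A-to-N per VR; half of replaced adenines
  become guanine) so the whole pipeline is testable against known
  truth.

## Worked example

```r
library(dgrfinder)

# train the six submodels (3 TR + 3 RT) on the synthetic world
models <- train_models(
  simulate_training_set("TR", n = 60, seed = 1),
  simulate_training_set("RT", n = 60, seed = 2))

# a 20 kb genome with one implanted BPP-1-like cassette
g <- generate_dgr_genome(seed = 7, total_length = 20000)
res <- run_pipeline(dgr_config(models), g$contig)

res$counts$intact
#> [1] 1
res$records[[1]]$cassette_signature
#> [1] "VR>,TR>,RT>"
res$pairs[, c("vr_start", "vr_end", "length", "identity",
              "a_to_n", "non_a_to_n", "longest_ccs")]
#>   vr_start vr_end length  identity a_to_n non_a_to_n longest_ccs
#> 1     9561   9669    108 0.9166667      9          0          33
```

One intact DGR is called: the cassette reads VR→TR→RT left to right on
the forward strand (the prototypical layout), and the recovered TR–VR
pair differs at 9 positions, all of them TR adenines (`a_to_n = 9`,
`non_a_to_n = 0`) — the DGR hallmark. `identity` counts identical
aligned columns over all columns and `longest_ccs` is the longest
identical ungapped stretch between the two repeats.

A command-line wrapper with `simulate`, `train`, `scan`,
`validate-reads` and `cluster` subcommands is installed as
`exec/dgrfinder`.

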
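---
title: "Quality-weighted alignment-free measures: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-weighted alignment-free measures: model, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerq)
```

## The problem

Two sequencing samples — each a bag of reads from an unknown genome or a
mixture of genomes — are to be compared without assembling anything and
without a reference.  Word-count (alignment-free) statistics do this by
summarizing each sample as a vector of k-mer counts and comparing vectors.
The twist this package implements: sequencers also report, per base, a
phred quality score `Q = −10 log10 P(error)`, and that information can be
folded into the counts themselves, so that unreliable k-mer occurrences
count less.

## Model

**Counting.** Reads are supplemented with their reverse complements (a
read may come from either strand), and all overlapping windows of length
`k` are tallied into `X_w`.  Windows containing `N` are skipped entirely:
an ambiguous base has neither a meaningful identity nor a meaningful
quality, and partial credit would break the count/expectation pairing.
Because each window of a complement read mirrors a window of its original
with the same bases and the same (reversed) qualities, the tally satisfies
`X_w = X_{w̄}` exactly, and the package exploits this by counting one
strand and folding.

**Null model.** Centralization needs `p_w`, the null probability of `w`.
We estimate an order-0 model from the nucleotide frequencies of the two
samples being compared, pooled and strand-symmetrized, and set
`p_w = Π f(w_i)`.  Pooling per pair (the default; a global pooled model is
a flag) matches the pairwise posterior quality estimator below.  The
expectation of a count is then `W (p_w + p_w̄)`, with `W` the number of
original-read windows — `M(β−k+1)` for uniform reads, `Σ(len−k+1)` in
general, minus skipped ambiguous windows.

**Quality weighting.** An occurrence's correctness probability is
`P = Π_{j<k} (1 − 10^(−Q_j/10))` (independent errors within a read — the
standard assumption).  `X^q_w` sums these instead of 1.  The expected
correctness of an occurrence of `w`, `E(P_w) + E(P_w̄)`, cannot be derived
from a machine model (quality distributions are instrument-specific), so
it is estimated by the posterior relative frequency
`(X^q_w + Y^q_w)/(X_w + Y_w)` over the pair — defined exactly for the
words the sums run over (see below).

**Statistics.** Four raw statistics (`D2`, `D2*`, `D2^q`, `D2^q*`) and
four normalized dissimilarities.  The normalization is
`½(1 − raw/(√selfX · √selfY))`, i.e. half of one minus a cosine: 0 for
identical profiles, ½ for orthogonal ones, 1 for anti-correlated
centralized profiles.  The starred self-norms are `Σ X̃²_w / p_w`.

## Numerical and definitional choices

* **Dissimilarity orientation.**  The source lineage prints the d-type
  normalization as `½(ratio)`, which makes identical samples score ½ and
  anti-correlated ones 0 — unusable as a distance fed to UPGMA, and in
  contradiction with clustering identical samples at height 0.  We
  implement `½(1 − ratio)`; the literal printed form is available as
  `literal_d2 = TRUE` / `--literal-d2-formula`.
* **Word universe.**  Starred sums and self-norms run over the words
  observed in at least one of the two samples, not all `4^k`: for
  unobserved words the posterior expectation is 0/0, and their centralized
  products would inject pure background signal.  This matches what a
  streaming counter can compute in one pass.
* **Self-norm denominator.**  The printed self-norms divide by `p_w`, not
  `p_w + p_w̄`, and we follow the letter.  One measurable consequence:
  when all emitted qualities are equal (constant error rate),
  `X^q_w = c·X_w` with `c = (1−p)^k`, and `d2^q*` becomes an exact affine
  transform of `d2*` — average-linkage trees are then identical.  Quality
  weighting can only help when qualities vary per base, which is also true
  of real instruments.
* **Unequal samples.**  Each sample is centralized with its own window
  total; the shared scale uses the geometric mean `√(W_X W_Y)`, which
  keeps the matrix symmetric and reduces to `M(β−k+1)` for equal samples.
* **Determinism.**  Words are accumulated in a fixed (lexicographic code)
  order; repeated runs are byte-identical.
* **Degenerate inputs.**  An empty k-mer profile (self-norm 0) and a
  background inconsistent with the data (`p_w = 0` for an observed word)
  raise errors rather than NaNs.  A `Q = 0` base makes every window
  containing it contribute weight 0, as it should: the scale says such a
  call is certainly wrong.

## Parameters that matter

| parameter | default | meaning / guidance |
|---|---|---|
| `k` | 7 (compare), 8 (metagenome) | word length; the useful range centers near `log4(N)` — the length at which a word is expected about once in a sequence of length `N` (`log4(5000) ≈ 6.14`); `expected_unique_kmer_length()` computes it |
| `phred_offset` | 33 | FASTQ dialect; 64 for legacy Illumina |
| `background` | pooled | null model per pair; `global` pools all samples |
| `mismatch_prob` | 0.1 (reads) | per-base substitution rate of the simulator; 0.1 emulates a noisy/long-read regime, 0.01 a clean short-read one |
| `relatedness` | 70 | expected substitutions per 100 sites per unit tree height of the clock; 70 is a high-divergence regime, 10–20 a comfortably recoverable one |
| coverage | `βM/N` | tree recovery is reliable from ~15×; below ~5× the centralized, quality-weighted measure degrades most gracefully |

## What the simulator emulates — and what it does not

`evolve_family()` draws a random bifurcating **ultrametric** topology
(sequential random joins, the j-th at height `j/(n−1)`) and applies
uniform point substitutions along each edge at `relatedness/100` per site
per unit height, plus optional single-base indels.  The clock makes the
truth recoverable by UPGMA, the reference method here; an edge-count-based
load on a non-clock topology would not be.  The spec-level contract — two
leaves joined at the root are `2·relatedness/100` expected substitutions
apart — is preserved.  Not emulated: PAM-style rate matrices,
transition/transversion bias, site rate heterogeneity, realistic indel
length distributions.  Composition-based measures see none of these
directly, but absolute tree-error magnitudes from richer simulators will
differ; only trends and regimes transfer.

`sample_reads()` draws uniform start positions and strands and flips each
base with probability `p_i`, emitting `Q_i = round(−10 log10 p_i)` — i.e.
qualities are *calibrated by construction* (the empirical error rate among
bases emitted at `Q` sits within one phred unit of `10^(−Q/10)`; this is a
tested invariant).  The default profile is constant; `profile = "ramp"`
varies the rate geometrically from `p/f` to `p·f` along the read
(log-mean `p`, default `f = 5`), emulating 3' quality decay.  Not
emulated: position-specific empirical error curves, indel errors,
miscalibrated or quantized quality tables, paired ends.  A green test on
this generator therefore establishes that the measures exploit *correct*
quality information; it does not establish robustness to instruments that
lie about their qualities.

`make_metagenome()` mixes reads from several genomes under an abundance
profile; `make_metagenome_pair()` builds the three canonical two-type
designs (disjoint genomes, partially shared, same genomes with different
abundances) over synthetic random genomes.  Real communities add shared
homology between distinct species, uneven GC and genome sizes — all absent
here, which makes the disjoint-genome design easier than its real-world
counterpart.

## Evaluation protocols

`run_phylogeny_benchmark()` evolves a family, samples reads per leaf,
builds all-pairs matrices, UPGMA (or NJ) trees per measure, and scores
each against the truth with the Robinson–Foulds distance, averaged over
replicates.  `run_metagenome_benchmark()` samples replicate metagenomes of
two types, clusters the `d2^q*` matrix with average linkage, and reports
the fraction of samples assigned to their type at a two-cluster cut plus
the merge height of the node separating the types — the higher that node
relative to the merges below it, the cleaner the separation.

Two regimes are pinned by the test suite: at coverage 15 and 1% error a
10-leaf family is recovered exactly (mean RF 0 over 5 seeds); at coverage
5 and 10% error with ramp qualities, the quality-weighted starred measure
is at least as accurate on average as its unweighted counterpart over 10
replicates.  The two-type disjoint-genome metagenome design (10 samples of
20,000 × 150 bp reads at 1% error, `k = 8`) is classified at 100% accuracy;
this is the number `scripts/acceptance.R` recomputes.

## Known limitations

* Order-0 null model only (the `background_model` contract leaves room for
  higher Markov orders, but none is implemented).
* `k ≤ 26` (word codes are exact doubles); dense tallying internally, so
  memory grows as the observed-word count, not `4^k`.
* The d-type `[0,1]` range is guaranteed by Cauchy–Schwarz for `d2`/`d2^q`
  and for `d2*`; for `d2^q*` the printed `p_w` self-norms leave a
  theoretical gap when the posterior expectation falls below ½ (error
  rates above `1 − 0.5^{1/k}`); in all tested regimes values stay in
  range.
* UPGMA assumes (approximately) clocklike dissimilarities; for strongly
  non-clock data use `neighbor_joining()`.
* The simulator does not model indel sequencing errors; quality strings on
  indel-bearing reads from real instruments shift frames in ways point
  substitutions do not.
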
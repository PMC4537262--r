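---
title: "Methods: pan-genome openness, core additions, compatibility and ANI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome openness, core additions, compatibility and ANI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangenomics)
```

## The model and the objects

The package analyses a set of bacterial genomes through their *ortholog
occurrence matrix*: strains in rows, ortholog groups in columns, cell values
the number of member genes (so paralogs are counted, while most analyses use
the binary presence view). The matrix is typically produced by an external
orthology clusterer and read from its "groups" text format
(`read_groups()`), or from a plain TSV (`read_matrix_tsv()`). Orthology
inference itself is out of scope.

Groups partition into **core** (present in all n strains), **moderately
common** (2 to n−1 strains) and **rare** (exactly one strain). With a single
strain both the core and the rare definitions apply; core wins — a
one-genome "pan-genome" is all core. This precedence is arbitrary but
documented and tested.

## Accumulation curves and the Heaps/power-law machinery

`accumulate()` draws random orders of sequential strain inclusion
(Fisher–Yates permutations from one seeded generator) and records, for each
prefix of k strains, the pan-genome size `pan(k)`, the core size `core(k)`
and the number of newly seen groups `new(k) = pan(k) − pan(k−1)`. For n ≤ 8
all n! orders are enumerated instead, which makes exact means available on
toy matrices and gives the sampled mode an internal oracle (they must agree
within Monte-Carlo error, and the suite checks this at 3·SE).

The implementation does not re-scan the matrix per prefix: for each order it
computes, per group, the first inclusion step at which the group is present
(yielding `new` and `pan`) and the first step at which a strain lacking it
appears (yielding `core`), which is O(n·G) per order.

Fitted models:

* `fit_power()`: y = k·xᵅ, nonlinear least squares on the original scale,
  initialized from the log–log regression; R² is reported on the original
  scale. Zero-residual data are handled through the `scaleOffset`
  convergence control; if the optimizer still fails the log–log
  initialization is returned flagged `converged = FALSE`.
* `fit_core()`: y = K·xᵃ + b·x + c for the core curve. The surface is
  multimodal in `a`, so fitting multi-starts at a ∈ {−0.5, −1, −2}; at each
  start the linear-in-(K, b, c) profile gives the remaining initial values,
  and the best SSE wins.

`classify_openness()` labels a new-gene fit *open* when −1 < α < 0 and
*closed* when α ≤ −1; the boundary goes to closed because the open criterion
is strictly inside the interval. `strains_to_threshold()` inverts the fit
exactly: the smallest integer N with k·Nᵅ ≤ t, with a guard against
floating-point slop on either side of the analytic ceiling (skipped above
2⁵², where N−1 is no longer representable).

**The k = 1 point.** The first point of the new-gene curve equals the mean
per-strain group count and therefore mixes core and accessory content; the
later points are purely accessory turnover. Fits include all points by
default, but every openness-regime check in this package fits from k = 2
(`drop_first` in `jackknife_alpha()`, explicit `x = 2..n` elsewhere).
The published amplitude this package's conventions are matched against
(a new-gene amplitude of ~470 for matrices whose average strain carries
~2000 groups, with R² ≈ 0.998) is only consistent with the first point being
excluded, so this is treated as the field convention rather than a free
choice.

`jackknife_alpha()` repeats the whole pipeline on delete-half subsamples
(⌈n/2⌉ strains kept, uniformly without replacement), refits the new-gene
power law on each subsample's mean curve, and returns the exponent
distribution. Defaults are 2000 subsamples with 1000 permutations each; both
are arguments, and much larger designs are possible where time allows.
Subsample seeds are drawn up front from one seeded stream, so the procedure
is reproducible and could be parallelized by subsample. Subsamples whose
mean new-gene curve touches zero (e.g. identical strains) cannot be fitted
on the log scale; they are skipped and counted.

## Core additions and their null

A *core addition* of a strain subset S is the set of groups present in every
member of S and absent from every other strain (`core_addition()`, binary
presence, paralog multiplicity ignored). The null distribution
(`core_addition_null()`) enumerates all C(n, m) subsets of size m
exhaustively — cheap for the study designs this targets (C(28, 2) = 378) —
optionally excluding the observed subset of interest, which mirrors the
"all other random divisions" convention; a sampling mode covers larger
designs, and the suite checks its mean against the exhaustive mean at 3·SE.

## Compatibility (four-gamete) scoring

Each group's presence pattern is a binary character. Two characters are
*incompatible* when all four joint states occur — evidence of homoplasy or
recombination under the infinite-sites view. `compatibility_summary()`
scores all pairs of parsimony-informative characters (both states in ≥ 2
strains; constant and singleton characters carry no signal and are excluded
by default). The optimized path computes the four joint-state indicators for
all pairs at once via crossproducts; the test suite pins it to a literal
joint-state tabulation on 50×200 matrices. Because no particular null is
canonical here, the permutation null is stated explicitly: each character is
shuffled across strains independently, preserving gene frequencies and
destroying linkage, and p = (1 + #{null ≥ observed}) / (1 + n_perm).

## Fragment-based ANI

`ani_pair()` implements the classical fragment/BLAST recipe: the query is
cut into 1020-bp windows per contig (no chimeric fragments across contig
breaks; a trailing fragment is kept when ≥ 100 bp — the cutoff is
configurable since published pipelines do not document it). Each fragment is
locally aligned to the reference; per fragment the *overall identity* is
identities divided by the full fragment length and the *alignable fraction*
is the aligned fragment span divided by fragment length. Matches with
overall identity > 30% and alignable fraction ≥ 70% are retained, and ANI is
the mean local identity (identities / alignment length) of retained
matches, in percent.

Two aligners satisfy the same contract. The default *internal* aligner finds
exact k-mer seeds (`Biostrings::matchPattern`), picks the best-supported
diagonal, and runs a local `pairwiseAlignment` against a padded window; it
is dependency-free and adequate for the synthetic substitution/indel pairs
the generator produces. The *blastn* adapter shells out to
`makeblastdb`/`blastn` with classical ANIb scoring (reward 1, penalty −1,
no dusting) and is the route to use when agreement with published
BLAST-based numbers matters. `ani_matrix()` computes both directions,
reports their mean (published tables print a single number per pair without
stating a direction), and clusters on 100 − ANI with complete linkage.

## Sequence statistics and profiles

`gc_content()` is (G+C)/(A+C+G+T) with ambiguous bases excluded from the
denominator. `length_summary()` sums contig lengths per genome and compares
labeled groups with a two-sided Mann–Whitney U test; for small samples
(min(n₁,n₂) ≤ 8) the exact distribution is enumerated over all
C(n₁+n₂, n₁) assignments with midrank ties — written in-house because the
stock test refuses exact p-values under ties — and cross-checked against the
stock implementation on tie-free data.

Glycoside-hydrolase profiling excludes families GH23, GH25, GH73 and GH103
by default: these are peptidoglycan hydrolases/lyases whose counts track
prophage load rather than carbohydrate metabolism. PCA always mean-centers
and optionally unit-scales (zero-variance families dropped first); component
signs follow a deterministic convention (largest-magnitude loading
positive), so results are reproducible across strain orderings up to that
convention. Family distribution differences across subspecies use
Kruskal–Wallis with Holm–Bonferroni adjustment; constant families get p = 1
by convention. Functional-class enrichment across the core/moderate/rare
partition uses two-sided Fisher exact tests on 2×2 tables (class vs rest,
cell vs rest) over *annotated* groups only, with Benjamini–Hochberg control
across all class × cell tests.

## The synthetic generator: what it emulates and what it does not

`simulate_pangenome()` produces binary matrices with a fixed core and one of
two accessory models:

* **beta-spectrum(a, b, n_accessory)** — per-group frequency p ~ Beta(a, b),
  presence Bernoulli(p) i.i.d. per strain. Strains are exchangeable, which
  is exactly the assumption the permutation accumulation machinery makes, so
  this is the matching null for calibration tests (e.g. the uniformity of
  the compatibility permutation p-value). The spectrum converges to the
  Beta law (KS < 0.05 at 10⁴ groups in the suite).
* **open-stream(θ, f)** — each strain seeds θ new candidate groups, each
  retained in every later strain independently with probability f. This
  yields Heaps-like accumulation with a tunable exponent. The preset used in
  tests (θ = 120, f = 0.25, n = 20, core 1200) was chosen once to resemble a
  realistic draft-genome study: ~2000 groups per average strain, a core of
  ~1200, and a new-gene exponent near −0.9 — inside the open regime — when
  fitted from k = 2.

Neither model has phylogenetic correlation, gene-linkage structure,
rearrangements, or annotation error; a green test therefore establishes
correctness of the *computations* on exchangeable or stream-structured
matrices, not that any real data set is open or closed.

`simulate_genome_pair()` generates an i.i.d. ancestor at a target GC
(G and C equiprobable) and derives a partner by i.i.d. substitutions
(uniform over the three alternatives — no transition/transversion bias,
which is sufficient for ANI recovery) and optional single-base indels. At
2% substitutions the expected ANI is 98.0% up to binomial error
(back-substitution is impossible in a single step by construction), giving
the ANI stack a closed-form oracle.

## Numerical choices and degenerate inputs

* Permutations come from R's seeded generator; all user-facing entry points
  take a `seed`.
* Exact accumulation replaces sampling at n ≤ 8 (40320 orders at most).
* Marker-locus selection measures spacing between closest gene ends — the
  conservative reading of "more than 10 kb apart" — and resolves conflicts
  greedily by descending length with positional tie-breaks, so output is
  deterministic and order-invariant.
* An undefined ANI (no retained fragments) is flagged, and such pairs are
  dropped from clustering with a warning rather than imputed.
* `fit_power` refuses y ≤ 0 (log-initialization impossible); jackknife
  subsamples hitting that case are skipped and counted.

## Scaling in the test suite

Published designs of this kind use 10⁴ permutations and up to 5×10⁴
jackknife subsamples. The suite and acceptance checks scale these down
(50–2000 permutations, tens of subsamples, 200 openness replicates) to run
in minutes; all Monte-Carlo assertions use 3·SE bands, so the reduction
widens tolerances without biasing means.

## Known limitations

* The internal ANI aligner is desk-scale: exact seeds plus banded local
  extension. For distant pairs (< ~80% identity) seed misses inflate the
  undefined-fragment rate; the blastn adapter is the right tool there.
* The shared-ortholog heatmap counts binary presence; whether paralog
  multiplicity should enter is genuinely ambiguous and documented as a
  choice.
* Openness classification inherits all caveats of Heaps-law extrapolation:
  it is a statement about the fitted curve, not about biology beyond the
  sampled strains.
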
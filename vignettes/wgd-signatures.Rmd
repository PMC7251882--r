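---
title: "Detecting whole-genome duplication signatures: models and methods"
author: "wgdsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting whole-genome duplication signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdsig)
```

# The problem

A genome that went through a whole-genome duplication (WGD) carries a
characteristic triple signature in its present-day gene complement:

1. a cohort of paralog pairs of *the same age*, visible as a distinct
   interior peak in the distribution of pairwise synonymous distances
   (Ks) across the whole paranome, on top of the L-shaped background
   produced by continuous small-scale duplication (SSD) and loss;
2. *co-linear duplicated blocks* — runs of paralogous genes in conserved
   order — whose anchor pairs date to that same peak and which, in
   fragmented assemblies, reside predominantly on *different* scaffolds
   (the duplicated chromosomes were fragmented independently);
3. under a phylogenetic birth-death model of gene-family counts, a
   *decisively non-zero retention rate* `q` for a WGD hypothesis placed
   on the corresponding species-tree branch.

Each individual signal has failure modes: recent segmental-duplication
bursts also create co-linear blocks (but without a matching paranome
peak, and often within one scaffold as tandem arrays or palindromes);
uncollapsed haplotigs mimic duplicated segments (but at roughly half
read depth); and elevated duplication rates can masquerade as retention
at a WGD node. `wgdsig` implements all three lines of evidence, the
guards against their failure modes, and a synthetic genome-evolution
generator so each stage can be validated against known ground truth.

# The Ks machinery

Paralog families are delineated by Markov clustering (inflation 2.0 by
default) of the all-vs-all within-proteome similarity graph, ingested
from the conventional 12-column tabular format with an E-value cutoff
of 1e-10 (1e-5 in the relaxed regime). `cluster_paralogs_mcl()`
implements the expansion/inflation iteration directly (pruning
threshold 1e-5, at most 100 iterations) and discards singletons.

For each family, a protein-guided codon alignment is obtained by
back-threading (`backthread_codon_alignment()`): every aligned
amino-acid column maps to its codon, columns containing any gap are
stripped, and internal stop codons are rejected. Pairwise Ks is then
estimated by maximum likelihood under the Goldman-Yang codon model with
F3x4 equilibrium frequencies (`estimate_ks_pair()`), optimizing
divergence, transition/transversion ratio and omega by bounded
quasi-Newton search on log parameters from three starts. The distance
`t` (substitutions/codon) is decomposed into Ks and Ka via the
synonymous flow of the fitted generator relative to the
mutational-opportunity flow at omega = 1; identical sequences
short-circuit to the boundary MLE Ks = 0; estimates beyond Ks = 5 are
flagged saturated. At 1,000 codons the estimator is unbiased with
roughly 9% sampling noise at intermediate Ks, which is why validation
averages a few replicates per distance.

Because large families would otherwise dominate the age distribution,
events are *node-weighted* (`weight_ks_by_node()`): each internal node
of the family tree is one duplication event; the pairs whose most
recent common ancestor is that node share it, each carrying weight
1/(pairs at the node), so every event contributes unit mass. Family
trees can be supplied (newick, from any external tree program) or built
by neighbor joining on protein p-distances and midpoint-rooted — only
the LCA structure matters. Saturated pairs are excluded before node
averaging by default (the alternative order is available behind a
flag), no within-node trimming is applied, and events with consensus
Ks = 0 or > 5 are removed (`filter_ks_events()`).

# Peaks and the decision framework

`detect_ks_peaks()` estimates a Gaussian-kernel density of the weighted
events with a Silverman bandwidth floored at 0.05 Ks, *reflected at
Ks = 0* so that smoothing cannot push the L-shaped SSD boundary mode
into the interior. Interior modes (beyond the 0.1 boundary-exclusion
window) qualify as peaks when their topographic prominence exceeds 10%
of the maximum interior density. These two constants make the visual
notion of a "distinct peak" explicit; both are configurable, and on
simulated pulses (mean 0.8, sd 0.1, 25% mass) the detector localizes
the peak within 0.05 while pure exponential-decay simulations yield
zero interior peaks.

The verdict (`assess_duplication_signature()`) is a pure function of an
explicit evidence record: `WGD_consistent` requires an interior
paranome peak, at least 50% of anchor-pair Ks mass inside the peak's
supporting interval, and at least 50% of blocks on different scaffolds;
blocks failing either condition give `segmental_burst`; no blocks and
no peak give `SSD_like`; anything else (e.g. a peak without blocks) is
`inconclusive`. The 50% thresholds are declared defaults, not inferred
constants, since the underlying criterion is qualitative.

# Co-linearity

`chain_collinear_blocks()` places within-genome homolog hits in the
gene-rank grid of every scaffold pair (self-pairs keep one canonical
copy of each hit and mask the trivial diagonal) and chains them by
sparse dynamic programming: 50 per anchor, a penalty of 1 per unit of
rank-space Manhattan distance between consecutive anchors, extension
allowed only while that distance stays within `max_gap`, strict rank
monotonicity on both copies (increasing = parallel, decreasing =
inverted). Chains are extracted best-first by score, then length, then
first-anchor order (parallel preferred on exact ties); extracted
anchors cannot be reused. The stringent preset uses seed size 5,
`max_gap` 25 and E <= 1e-10; the relaxed preset seed size 3, `max_gap`
40 and E <= 1e-5. "Manhattan distance" is interpreted in gene-rank
units — a declared reading, since a tool-specific gap count would be
equally consistent with the phrase. The implementation is checked
anchor-for-anchor against exhaustive chain enumeration on small grids.

Block topology follows directly: different scaffolds give
`inter_scaffold`; intra-scaffold blocks are `palindrome` when inverted
and `tandem_array` when parallel (the inverted-orientation reading of
"palindrome" is a declared criterion). Pair classification assigns
`segmental_anchor` to anchors, `tandem` to non-anchor same-scaffold
pairs within one rank (configurable), and `dispersed` otherwise, with
anchor > tandem > dispersed precedence. Note that reversing the
coordinate system of *one* scaffold flips the orientation of
inter-scaffold blocks that touch it while preserving membership and
intra-scaffold topology; reversing every scaffold at once is a
symmetry of the labels.

# The haplotig coverage test

For each co-linear block interval, `block_coverage_test()` compares the
mean per-base depth to the distribution of means of 1000 random
same-length regions (sampled uniformly over scaffolds weighted by
eligible start positions). Two normal-assumption intervals are
reported: the distributional interval mean ± 1.96 sd of region means,
and the standard-error interval of the background mean; empirical
2.5/97.5 percentiles accompany both. The *distributional* interval
drives the flag, so that under the null a region is flagged at the
nominal one-sided 2.5% rate — a standard-error interval would flag
nearly half of all null regions and cannot be the operative bound. A
contig-based variant (sampling whole contigs rather than length-matched
regions) reduces to supplying contig-sized intervals.

# The DL+WGD gene-count model

Family counts on a dated species tree evolve by a linear birth-death
process: each gene lineage duplicates at rate `lambda` and is lost at
rate `mu` (events/gene lineage/My) along every branch; at a
hypothesized WGD every gene independently gains a retained copy with
probability `q`; the root count follows a geometric prior on {1, 2,
...} with parameter `eta` (mean 1/eta — families must be non-empty at
the root, a declared convention since the support is not otherwise
pinned down). This is a *count-level* likelihood: the same generative
model, priors, filters and hypothesis tests as a gene-tree
reconciliation analysis, evaluated on family counts instead of
amalgamated gene-tree posteriors. Conditional-clade-distribution
amalgamation is an explicit non-goal; conclusions about *statistical
support for WGD retention* transfer, per-reconciliation event maps do
not.

The transition kernel (`bd_transition_probability()`) uses the
classical closed form with sign-aware log-space accumulation (the
`1 - alpha - beta` factor goes negative at large rate-time products)
and analytic critical and pure-birth/death limits; full matrices on
states 0..N are built by iterated convolution of the single-lineage
row, which keeps all truncated entries exact. The family likelihood
(`family_loglikelihood()`) is a pruning recursion over the tree,
vectorized across families, with per-family rescaling; the root is
marginalized over the geometric prior and the result is conditioned on
the family-inclusion event (at least one survivor in each root clade)
via closed-form extinction generating functions. Truncation defaults
to 4 x max observed count + 10 with loud failure when reachable-state
probability mass leaks beyond 1e-6.

Families are first filtered (`filter_families()`): root-clade presence
first, then the Poisson outlier rule Y = 2 sqrt(X) > median(Y) + 3
computed over the root-filter survivors (the order is a declared
choice). Three prior structures are available: constant
(Exponential(mean 0.005) rates, Beta(10, 2) on eta), hierarchical
independent log-normal branch rates (Exponential(mean 0.5) means,
InverseGamma(5, 1) variance), and a geometric-Brownian-motion prior
with nu = 0.1 and drift -nu^2 t / 2 (the martingale convention).
Retention rates are uniform on [0, 1]. Sampling is blockwise adaptive
random-walk Metropolis on log/logit scales with adaptation frozen after
burn-in; the full-scale regime is 11,000 iterations with 1,000 burn-in,
with pilot chains on 1,000-family subsets available, and the two
root-adjacent branches can be constrained to share rates.

## Known interactions worth understanding

The outlier filter truncates exactly the large families the likelihood
does not condition on. Two visible consequences on simulated data:
`eta` is biased upward (large root counts are censored), and a WGD
whose retained copies inflate many species' counts — a deep-branch
event over a large clade — has its `q` pulled downward because its
most informative families are preferentially censored. On a terminal
branch the effect is minor, and recovery there is clean: with 600
families simulated at q = 0.3 the posterior interval covers the truth,
and without a simulated WGD the interval collapses onto zero. Duplication
and loss rates themselves recover within a few percent either way. This
is a property of the published filtering-plus-conditioning procedure,
reproduced deliberately; users comparing hypotheses on deep branches
should read `q` estimates with the filter in mind. Retention posteriors
can also be multimodal (a mode at q = 0 traded against an elevated
duplication rate); `summarize_wgd_support()` flags this rather than
hiding it.

# The synthetic generator

The generator is the test bed for every stage and encodes the study
conditions the package is validated under:

* `simulate_family_counts()` — exact per-lineage Gillespie realization
  of the DL+WGD process (yielding a replayable event log), defaults on
  a 9-taxon dated tree with calendar-time depths typical of arthropod
  divergences and rates of 0.002 events/gene lineage/My — the order of
  magnitude typical of insect small-scale duplication and loss — and
  eta = 0.8.
* `simulate_paranome_ks()` — SSD background with exponential survival
  per unit Ks (a modeling convention: the L-shape pins down
  monotonicity, not a law; the hazard default 1.5/Ks gives the strongly
  recent-skewed age profile typical of paranomes) plus Gaussian WGD
  pulses truncated to (0, 5], e.g. mean 0.8, sd 0.1, as in the
  horseshoe-crab-like archetype.
* `simulate_genome_layout()` — planted co-linear blocks of chosen
  topology, tandem duplicate pairs and dispersed pairs, with a guard
  gap (default 45 genes) between features exceeding any chaining
  `max_gap` in use so that planted features can never merge into one
  chain; dispersed pairs are placed randomly and cross-scaffold so they
  cannot fake co-linear runs or tandem adjacency.
* `simulate_coverage_track()` — negative-binomial depths (variance
  m + phi m^2; phi = 0 is exactly deterministic) with half-depth
  haplotig segments.

What the generator does *not* emulate: sequence-level evolution along
trees (indels, rate heterogeneity, codon bias), transposable elements,
assembly errors other than uncollapsed haplotigs, gene conversion, and
rediploidization-driven erosion of co-linearity. Passing the suite
therefore shows the machinery is correct under the stated generative
assumptions, not that real genomes satisfy those assumptions.

# Numerical choices and problem sizes

Defaults chosen once and used throughout: MCL pruning 1e-5, max 100
iterations; GY94 optimizer bounds t in [1e-4, 30], kappa in [0.1, 50],
omega in [1e-3, 20], three starts; KDE bandwidth floor 0.05 Ks,
boundary window 0.1 Ks, prominence 10%; histogram bins right-closed
with conservation of mass to 1e-9; truncation leak bound 1e-6;
adaptation target 0.3 acceptance. The validation suite runs at desk
scale: 1,000 simulated families for constant-rate recovery and 600 for
retention-rate recovery with chains of 1,200 iterations (300 burn-in),
200 random grids for the chaining oracle, 50 planted layouts for the
round trip, and 500 replicates for the coverage null — sizes chosen so
the whole suite validates every stage in well under half an hour on one
core while keeping Monte-Carlo noise far below the asserted tolerances.

# Workflows

`run_genome_workflow()` chains ranking, co-linearity, classification,
Ks histogram and peaks, the coverage test and the verdict for one
genome, writing TSV/JSON artifacts and a parameter manifest;
`run_phylo_workflow()` runs filtering, the DL+WGD posterior and the
per-branch rate and WGD-support tables. `write_fixture_bundle()`
materializes the three archetypal scenarios (WGD-like, segmental-burst,
SSD-only) as on-disk bundles in the standard formats (GFF3, 12-column
tabular hits, TSV, bedgraph, newick) for pipeline-level testing.
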
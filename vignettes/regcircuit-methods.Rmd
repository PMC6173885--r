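---
title: "Methods: expression-conditioned networks, shared-TF nulls and master-regulator ranking"
author: "regcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-conditioned networks, shared-TF nulls and master-regulator ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regcircuit)
```

## The analysis model

`regcircuit` operationalises a regulatory-circuit analysis for the
situation where genetically identical embryos diverge phenotypically and
transcriptionally: a directed background network of experimentally
supported regulator → target interactions is conditioned on the embryos'
own expression data, candidate regulators are found as transcription
factors (TFs) shared by the subnetworks of a few genes of interest, the
rarity of that sharing is measured against an exact combinatorial null,
and candidate master regulators are ranked by directed graph distance.

The stages, and the assumptions they encode:

**Edge filtering.** An edge regulator → target of the background network
survives iff

* the regulator's abundance exceeds a detection threshold (default:
  strictly positive, the minimal defensible reading of "detected" for
  FPKM-like units);
* the target is called differentially expressed in the supplied DE table
  (DE calling itself is upstream of this package and consumed as input);
* the target's per-biological-replicate |log2 fold change| is at least
  0.4, after technical replicates are averaged arithmetically.

The filter deliberately conditions differential expression on the
*target* only; the regulator must merely be detected. The two
requirements come from distinct clauses of the filtering rule (TF
detected; gene differentially expressed with |log2FC| ≥ 0.4), and
requiring DE of the regulator as well would delete every path from a
constitutively expressed master regulator to its responsive targets —
precisely the signal the analysis looks for. A `require_regulator_de`
switch exposes the stricter reading.

**Per-replicate rule.** The fold-change and detection criteria are
evaluated per biological replicate and must hold in *at least one*
replicate by default (`replicate_rule = "any"`, i.e. the per-replicate
networks are merged by union). The intersection reading (`"all"`) is
available. We chose union as the default after a feasibility analysis of
the generative model this package itself assumes: with a latent
per-replicate regulator activity whose within-group standard deviation
(1.0) is comparable to the between-group shift (1.5), demanding
|log2FC| ≥ 0.4 in *every* one of three replicates rejects genuinely
planted effects in roughly a quarter to a third of simulated studies at
any effect size — an intersection over noisy replicates is a conjunction
of noisy events, and its miss rate compounds. Union keeps the filter's
false-negative rate compatible with recovering true circuits at realistic
noise, at the cost of admitting marginal edges that the downstream
degree-2 pruning and the quadruplet null are designed to absorb.

**Subnetwork recipe.** For each seed gene: take the neighbourhood up to
two levels ignoring edge direction (the genes of interest are mostly
*targets*; their regulators sit upstream and would be invisible to a
directed expansion), then prune in one fixed, ordered pass — (1) remove
every node, the seed included, with fewer than two connecting edges
within the subnetwork; (2) remove every remaining non-TF node except the
seed. Each stored directed edge counts once toward the degree (a
reciprocal pair counts twice, a self-loop once). The pass is *not*
iterated to a fixed point: the recipe is two steps in a stated order, and
we preserve it literally (an `iterate` flag exposes the fixed-point
variant for sensitivity analysis). A consequence worth knowing: the
recipe is not idempotent — erasing non-TFs at step 2 can drop a
surviving TF below degree 2, so re-running the recipe on its own output
may prune further. Tests therefore assert monotonicity and the TF
constraint, not idempotence.

The seed is exempt from the TF-pruning step only, and seeds are excluded
from shared-TF intersections even when a seed is itself a TF: the
analysis seeks regulators *of* the seeds, and a seed "shared with
itself" would inflate k without evidence of shared regulation.
`shared_tfs(..., exclude_seeds = FALSE)` computes the other convention.

**The quadruplet null.** The shared-TF count k of the observed seed
quadruplet is referred to the distribution of k over *all* quadruplets of
the general network, in two compositions: unrestricted (`any_nodes`), and
one TF with three non-TFs (`one_tf_three_nontf`), mirroring the observed
seed set. The null re-uses the identical subnetwork construction — the
only concession to scale is memoisation: each node's pruned-subnetwork TF
set is computed once via `build_seed_subnetwork()` and intersected per
quadruplet, which is arithmetic-identical to rebuilding it four times per
quadruplet. Enumeration is exhaustive and deterministic (lexicographic
over sorted node ids) by default; because C(n, 4) grows as n⁴, a
`max_quadruplets` cap switches to uniform sampling without replacement
(combination unranking of uniformly drawn lexicographic ranks), and the
provenance always records which ran and with what seed. The tail
probability is the plain fraction Σ_{j ≥ k} n_j / N, so
`tail_probability(d, 0) = 1` and the smallest attainable non-zero value
is 1/N.

**Distance ranking.** Distances are unweighted directed shortest-path
edge counts. A TF missing a directed path to *any* gene of interest is
excluded from the summed ranking rather than summed over fewer targets —
otherwise poorly connected TFs would be rewarded for unreachability; a
`partial_sums` mode reports them separately. Ties share a rank
(minimum-rank convention) and are listed alphabetically for determinism.
When a ranked TF is itself a gene of interest its self-distance is 0 (the
graph-theoretic convention); `exclude_self_targets` drops such TFs
instead, and the two totals differ by exactly the self terms, so either
convention can be reconstructed from the other.

**Path tracing.** Circuit reporting uses shortest paths on the
*undirected* projection from each gene of interest back to each circuit
TF. With several shortest paths, the lexicographically smallest node
sequence is returned and the number of alternatives reported; a
disconnected pair is data ("unreachable"), not an error.

## Companion statistics

* **Pfaffl ratio** `E_t^ΔCt_t / E_ref^ΔCt_ref` with ΔCt =
  mean Ct(control) − mean Ct(treated); the sign convention (ratio > 1 ⇔
  up in the treated group) is stated here because the equation is often
  cited without it. Efficiencies are validated into (1, 2.2].
* **Fixed reallocation randomisation test**: whole samples — each
  carrying its target and reference Ct together, hence "fixed" — are
  reallocated between the groups preserving group sizes; the two-sided
  statistic is |log ratio|. All C(n, n₁) distinct reallocations are
  enumerated when that count is within the permutation budget (default
  2,000); otherwise random reallocations are drawn and the observed
  allocation is counted into the null, so p ≥ 1/(n_perm + 1) and p is
  never zero. Note the discreteness at small n: with 3 vs 3 samples there
  are 20 reallocations pairing into 10 distinct |log ratio| values
  (complementary allocations give reciprocal ratios), so the smallest
  attainable p is 0.1 and rejection at α = 0.05 is impossible — a
  property of the design, not a bug. Calibration checks therefore use
  6 vs 6 (924 reallocations, minimum p ≈ 0.002), where the observed
  type-I rate lands inside the binomial band around 0.05.
* **Correlations**: Pearson r with 95% CIs via the Fisher
  variance-stabilising transform, `atanh(r) ± 1.96/√(n − 3)`, assuming
  Gaussian data; an entry is significant exactly when its CI excludes
  zero, which for this transform is equivalent to p < 0.05 two-sided.
  Pairwise-complete observations; zero-variance genes yield flagged NA
  entries rather than errors.
* **Enrichment**: upper-tail hypergeometric p via `phyper`, fold =
  observed / expected overlap, Benjamini–Hochberg step-up via `p.adjust`.
* **Proportions**: Fisher's exact test (two-sided by summed point
  probabilities) for 2×2; Pearson χ² without continuity correction, k − 1
  degrees of freedom, for 2×k.

## What the synthetic generator emulates

`generate_network()` plants a circuit inside a random background: a
master TF regulating two integrator TFs, and master + integrators each
regulating every gene of two disjoint modules (ten "lipid-like" genes
elevated with master activity, ten "neural-tube-like" genes suppressed by
it). Module genes are thus within two undirected hops of the master, and
every pair of module genes shares at least the two integrators — the
wiring whose recovery the pipeline is tested on. Random edges are Poisson
out-degree (mean 5) over 30 TF and 120 non-TF nodes.

`simulate_expression()` draws one latent master activity per biological
replicate, `a ~ Normal(group mean, 1)` with group means (WT, KO-N,
KO-NTD) = (0, 0, 1.5) — the defect group is the divergent one — and
scales module-gene means by `2^(±effect·a)` (effect 0.8 log2 units per
activity unit, so the planted KO-N vs KO-NTD shift is 1.2 log2 units)
with lognormal noise (sd 0.2 on the log2 scale) per technical replicate
(3 groups × 3 biological × 2 technical). The DE table records the *true*
group log2 fold changes with significance = |log2FC| ≥ 0.4, because DE
calling is an upstream tool's job and the pipeline consumes its calls.
`simulate_embryo_panel()` is the per-embryo analogue (15 embryos, 5 per
group) for correlation analyses: one activity per embryo induces positive
within-module and negative between-module correlations.
`simulate_qpcr()` writes Ct values exactly consistent with the Pfaffl
model (plus optional Gaussian Ct noise), so noiseless recovery is exact
by construction and noisy recovery measures propagation, not model error.

What passing on these data does *not* show: real background networks are
scale-free-ish and much larger (thousands of nodes), real fold changes
are not generated by a single latent factor, real DE calls carry
calling-error, and real FPKM noise is count-driven and
mean-dependent. The synthetic tests demonstrate correctness of the
operations and recoverability under the stated model — not performance
guarantees on any particular organism's data.

## Numerical and scale choices

* Gene identifiers are opaque, case-sensitive strings; no symbol mapping.
* Fold-change pseudocount defaults to 0; division by zero gives ±Inf,
  which compares correctly against the 0.4 threshold (an absent reference
  signal with a present test signal *is* an extreme fold change).
* All stochastic components (generators, null sampling, sampled
  reallocations) run under `withr::with_seed`: outputs are pure functions
  of (configuration, seed) and the session RNG stream is never disturbed.
* Determinism of reported orderings: quadruplets lexicographic, ranking
  ties alphabetical, path ties lexicographic by node sequence.
* Problem sizes used by the test-suite and acceptance runs — 10–25-node
  oracle networks, 20 generator seeds, 2,000 sampled quadruplets per
  null, 100 random reference quadruplets, 1,000 calibration datasets —
  were chosen so every oracle can be brute-force and the full suite runs
  in about a minute while keeping Monte-Carlo bands narrow enough to be
  meaningful (e.g. the binomial 95% band around 0.05 at n = 1,000 is
  ±0.0135).
* Grand-mean centering defaults to log base 2 with pseudocount 1, the
  common heat-map convention; both are arguments.

## Known limitations

* SIF export cannot represent isolated nodes; the node-attribute sidecar
  preserves them, and round-trip tests cover only (nodes-with-edges,
  edges) for the SIF path.
* The degree threshold interacts with the TF-erasure step (see
  non-idempotence above); interpret pruned subnetworks as the output of
  the recipe, not a fixed point.
* `shared_tf_distribution()` holds per-node TF sets in memory — fine up
  to tens of thousands of nodes, but exhaustive enumeration beyond
  ~2,000 nodes (≳ 10⁹ quadruplets) needs the sampling cap.
* The reallocation test assumes exchangeability of samples under the
  null; with technical replicates, average them first so the reallocated
  unit is the biological sample.
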
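---
title: "Coactivation network analysis of regional c-Fos densities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coactivation network analysis of regional c-Fos densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

## The inference problem

c-Fos immunoreactivity marks recently active neurons, so a table of
Fos-positive cell densities (cells/mm²) over brain regions and animals
is a one-shot snapshot of regional activation. Within one experimental
group, the across-animal Pearson correlation between two regions
estimates their functional coupling: animals in which region A was
unusually active also showed unusual activity in B. `fosnet` turns such
tables into group-wise coactivation networks and summarises their
architecture (hubs, communities, hierarchical modularity), with a
factorial ANOVA stage for the region-level mean contrasts that usually
accompany these studies.

The estimate is deliberately simple — a marginal correlation across a
handful of animals — and everything downstream inherits its limits:
with n = 5–9 animals per group, individual correlations are noisy
(Fisher-z standard error ≈ 1/√(n−3) ≈ 0.4–0.7), so the pipeline follows
the field's convention of fixed, high cutoffs rather than per-pair
significance testing, and all conclusions are about the thresholded
graph, not about any single edge.

## Pipeline stages and their parameters

### Correlation matrices

`correlation_matrix()` uses pairwise-complete observations so that a
region unquantifiable in one animal does not discard the animal
entirely. A region with zero variance across animals cannot be
correlated with anything; its row and column become missing values (and
are reported), never zeros — a zero would silently assert "no
coupling". Pairs supported by fewer than 3 complete observations are
flagged as low-support.

### Confidence networks

`threshold_network()` applies fixed cutoffs, defaulting to

| parameter | default | meaning |
|---|---|---|
| `low` | 0.79 | permissive positive network |
| `primary` | 0.83 | the main reporting network |
| `high` | 0.87 | strict positive network |
| `negative` | 0.83 | magnitude cutoff for the negative network |

These are conventions of the c-Fos connectome literature, not
statistical thresholds; they are stored in the run configuration
(`default_config()`), and the nestedness edges(high) ⊆ edges(primary) ⊆
edges(low) is asserted property-style in the tests. Published figure
legends sometimes use 0.78 for the low network and 0.87 for the
negative network; `default_thresholds("figures")` ships that preset so
neither convention is guessed silently.

### Centrality and composite hubs

Degree is counted on each binary network. Betweenness centrality is
computed on the binarised primary network with Brandes'
dependency-accumulation algorithm and normalised by (R−1)(R−2)/2, so a
node on every geodesic of a path graph scores exactly 1. Correctness is
anchored to an exhaustive oracle (geodesic counting via walk-count
matrices) over *all* connected graphs on up to 6 nodes plus random
graphs up to 12 nodes — agreement to 1e-10 — rather than to any
external library; an igraph cross-check is run where igraph is
available. Weighted betweenness is deliberately not the default: the
convention being reproduced reports a single betweenness column derived
from the thresholded graph.

A hub must reach the `hub_percentile` (default 80) for degree in the
low, primary *and* high networks and for betweenness on the primary
network. Percentiles use the nearest-rank method over all R regions
(cutoff = the ⌈p/100·R⌉-th smallest value) and ties at the cutoff
qualify; this makes the rule reproducible without interpolation
ambiguity, at the price that degenerate distributions (e.g. a
vertex-transitive graph) let every node qualify — the per-region
criterion trace in the `hub_report` makes such cases visible. A
`require_all_levels = FALSE` switch relaxes the degree condition to the
primary network only, since the field's wording varies on whether the
percentile applies per level.

### Spectral communities

Community detection maximises Newman modularity on the *weighted*
correlation network. By default negative correlations are removed
(`sign_policy = "positive_only"`): the positive and negative networks
are analysed separately elsewhere in the pipeline, and no signed
convention is implied by the source methodology. A signed variant
(Q⁺ − (m⁻/(m⁺+m⁻))·Q⁻, the asymmetric decomposition) is available by
flag.

The optimiser is classical: recursive bisection by the leading
eigenvector of the (sub)group modularity matrix, Kernighan–Lin
single-node fine-tuning after every split, stopping when no split
increases Q. Two determinism choices matter:

* the leading eigenvector is oriented so its first entry of magnitude
  > 1e-12 is positive, and exact-zero entries join the positive side;
* a final global refinement pass moves single nodes between (or out of)
  modules, each node at most once per pass, keeping the best
  configuration seen; among tied moves the candidate latest in
  column-major order wins, which prefers opening a new singleton module.
  The keep-best rule discards any exploration that fails to improve Q,
  so the tie-break only affects which optima are reachable, not
  monotonicity. This stage is what lets the method escape the known
  failure of pure recursive bisection on symmetric graphs whose optimal
  partition is odd-way (e.g. an 8-cycle).

Split gains below `min_gain = 1e-10` are treated as zero to guard
floating-point noise. Connected components are handled independently
and singletons become singleton modules. On every test fixture with ≤ 8
nodes the returned Q is required to reach 95% of the best Q found by
enumerating *all* set partitions, and the Q formula itself is checked
against a literal double sum to 1e-12.

### Hierarchical modularity

`euclidean_distance_matrix()` measures how differently two regions
correlate with the rest of the brain. The unit self-correlation entries
stay in the profiles by default (each pair then shares two constant
coordinates, a rank-preserving offset); `drop_diagonal = TRUE` removes
the pair's own coordinates, since the source convention is not stated.
Regions excluded for missing correlations are recorded so module counts
remain comparable across groups.

Complete linkage (`stats::hclust`) guarantees monotone merge heights,
so a fractional cut is well defined: `tree_cut(dend, f)` cuts at
f × (maximum merge height) *of that group's dendrogram* — per-group
normalisation, because each group's dendrogram is cut and the counts
are then compared across groups. Merges at exactly the cut height are
kept (≤ convention), which makes f = 1 always yield one module and
makes the boundary testable. `cut_profile()` profiles counts over
f = 0.50…0.95 in steps of 0.05, including the conventional primary cut
at 0.70; counts are non-increasing in f by construction and this is
asserted on random inputs.

### Factorial ANOVA

`factorial_anova()` fits the fully crossed fixed-effects model with
Type-III sums of squares under sum-to-zero contrasts (via `car::Anova`).
Type III is a documented choice: cell sizes of 5–9 make designs
unbalanced, the commercial packages typically used in this field report
marginal (Type-III-style) tests, and in balanced designs the choice is
moot (the tests assert Type III ≡ sequential there). A constant
response returns F = 0, p = 1 for every effect rather than an error.
Per-region analyses are *not* corrected across regions — only the post
hoc family is Bonferroni-corrected (p·m, capped at 1, pooled residual
variance) — and the report says so, so users can add an FDR step.
Power and calibration are simulation-tested: a planted 3-SEM effect at
n = 8/cell is detected with power ≥ 0.8, and the null rejection rate at
α = 0.05 stays inside its binomial 95% interval over 200 replicates.

## The synthetic cohort generator

The generator exists so that every stage has ground truth. It emulates:

* **Scale.** 60 named regions, a 2×2×2 factorial, group sizes cycling
  through 5–9 — the shape of a whole-brain c-Fos mapping study.
* **Marginals.** Densities are log-normal: positive, right-skewed, a
  reasonable stand-in for cell-count densities. Per-region means are
  log-spaced over 30–900 cells/mm² and the default coefficient of
  variation is 0.5, which at n ≈ 7 gives SEMs of roughly 10–30% of the
  mean, matching the dispersion such studies report. The distribution
  family itself is a modelling choice — density distributions are not
  published per animal — and nothing downstream depends on it beyond
  positivity and skew.
* **Dependence.** Correlation is planted on the latent Gaussian scale:
  a target matrix (within-module r, between-module r, hub rows boosted
  by `hub_extra_r`, capped at 0.99) is PSD-repaired by eigenvalue
  clipping followed by diagonal re-normalisation — simple and
  deterministic — and the latent draws are transformed per region.
  Pearson correlations of the densities themselves are slightly
  attenuated relative to the latent target (for CV = 0.5, r = 0.8 →
  ≈ 0.78); recovery tests therefore use the latent-scale target with
  tolerance, and the Monte-Carlo consistency check (n = 5000, maximum
  deviation < 0.05) is asserted on both scales.
* **Reproducibility.** One master seed; each group draws under a child
  seed obtained by stable string-hashing of its label, so adding or
  removing a group never changes the others' data. Identical inputs
  give bit-identical tables, and the full default pipeline run is
  byte-identical across reruns.

What it does **not** emulate: spatial structure within regions,
counting noise of the imaging step, sex effects, litter effects, or any
behavioural endpoint. Passing recovery tests therefore show that the
pipeline's inference chain is correct *under its own statistical
assumptions*, not that real cohorts of n = 5–9 animals identify true
hubs — at that sample size they generally cannot, which is visible in
the pipeline's own output on the default study.

### Recovery study designs

Two standing verification experiments are part of the test suite and of
`scripts/acceptance.R`:

* **Module recovery.** 3 planted blocks of 20 regions (within r = 0.8,
  between r = 0.1), n = 40 animals, 50 replicates; spectral communities
  and the 0.70 tree cut must both recover the blocks with mean adjusted
  Rand index ≥ 0.9, and agree with each other to the same level. n = 40
  rather than a study-realistic 5–9 because the question is whether the
  *methods* recover structure the data demonstrably contains. A share
  of tree-cut replicates lands at 2 instead of 3 modules: the r = 0.1
  background couples all 60 regions through a global factor whose
  sampling fluctuations at n = 40 can push one inter-block merge below
  the 70% cut — a real property of correlation matrices at this sample
  size, visible in the replicate spread.
* **Hub recovery.** One dense background whose realised density-scale
  correlation (latent 0.80 → ≈ 0.78) sits just below the low cutoff,
  with every fifth region's correlations boosted by 0.15 (latent 0.95 →
  ≈ 0.94, above the high cutoff). One region in five is planted because
  that is exactly the capacity of the 80th-percentile rule: recovery is
  then perfect precisely when the detector ranks every planted hub
  above every background region. Detected hubs must overlap planted
  hubs with mean Jaccard ≥ 0.8 over 50 replicates at n = 40.

## Orchestration

`run_pipeline()` validates the configuration before any computation
(thresholds strictly increasing, percentile in (0, 100), fractions in
(0, 1]), skips groups with fewer than 2 animals with a logged reason,
and writes per-group artefacts (correlation CSV, edge lists, node
metrics, hub JSON, module labels, merge table, cut profile) plus a
manifest holding the seed, the full configuration, a configuration
hash and per-group summary counts — enough to audit a run without
opening its outputs, and to re-run it exactly. Outputs contain no
timestamps, so reruns are byte-identical. File input accepts a wide
dialect (one CSV per group) and a long dialect (animal/group/region/
density), auto-detected from the header; negative densities and
duplicate (animal, region) pairs are rejected at parse time.

## Problem sizes in the test suite

The suite enumerates all connected graphs on ≤ 6 nodes for the
betweenness oracle, all set partitions on fixtures of ≤ 8 nodes for the
modularity oracle, 500 random inputs for each monotonicity property,
200 simulation replicates for ANOVA calibration and power, and 50
replicates for each planted-recovery study; the end-to-end determinism
check runs the full default study twice. These sizes keep the complete
suite under a minute on one core while leaving every assertion
oracle-backed.

## Known limitations

* Fixed correlation cutoffs ignore n; two groups with different sample
  sizes have different edge-inclusion error rates at the same cutoff.
  This mirrors the convention being implemented; per-n critical values
  would be a different method.
* Betweenness on a binarised graph discards weight information inside
  the thresholded edge set.
* Modularity maximisation has a resolution limit and the spectral
  optimiser is a heuristic; the exhaustive-oracle guarantee covers the
  small-graph regime, and the planted-recovery guarantee the
  well-separated regime, not arbitrary networks.
* The log-normal generator plants correlation on the latent scale;
  methods are scored against planted structure net of the (documented,
  small) attenuation, not against an empirical tissue model.
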
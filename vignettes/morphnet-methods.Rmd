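---
title: "Morphological similarity networks: models, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological similarity networks: models, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphnet)
```

## What the package computes

`morphnet` builds *single-subject* structural brain networks from gray-matter
(GM) density volumes. Instead of correlating regional summaries across a
group (classical structural covariance), it correlates the local 3D texture
of the cortex within one subject: the GM segmentation is tiled into
non-overlapping 3×3×3-voxel cubes, and the similarity of two cubes is the
maximum Pearson correlation of their 27 values over rigid rotations of one
cube relative to the other. Because a cube carries the local thickness and
folding pattern, two patches of cortex with similar morphology score high
even when their orientations differ. Cube-pair similarities are averaged
within pairs of atlas ROIs ("matrix resizing"), giving one symmetric
ROI × ROI matrix per subject, which is then Fisher z-transformed,
proportionally thresholded at a grid of sparsity levels, binarized, and
summarized with graph-theory measures. Group inference compares adolescents
with low versus high exposure to negative life events (NLEs).

## The cube similarity model

**Tiling.** The tiling grid is anchored at the low corner of the bounding box
of nonzero GM voxels, so the cube grid is determined by the data, not by the
array padding. Only complete cubes are kept; cubes with no GM content are
discarded (the minimum GM-voxel count is a config knob, default: keep a cube
if any voxel is nonzero — the most inclusive convention, since the upstream
segmentation already decides what is GM).

**Rotation set.** The 24 orientation-preserving symmetries of the cube,
represented as index permutations of the 27 voxel positions. Reflections are
excluded by default because they are not rigid motions of anatomy; a
48-element set including reflections is available behind a switch
(`rotation_set(include_reflections = TRUE)`). The maximum over relative
orientations of two cubes equals the maximum over rotations of one cube only
(group closure), so no double loop over both orientations is needed.

**Degenerate cubes.** A cube with zero variance (flat GM) has an undefined
correlation against anything; it scores 0 ("neutral") rather than being
dropped, which keeps cube counts and ROI pair counts stable across subjects.

**ROI assignment.** Each cube takes the majority atlas label among its 27
voxels, ties broken toward the smallest label, majority-background cubes
dropped. This is deterministic and order-independent, and handles real
atlases whose boundaries cut across cubes. (The synthetic atlas is built
from whole cubes, so in tests assignment is unambiguous by construction.)

**Resizing.** Entry (I, J) of the subject matrix is the arithmetic mean of
the rotation-maximized similarity over all cube pairs with one cube in each
ROI; the lower triangle mirrors the upper triangle and the diagonal is zero
(within-ROI similarity is kept only as a diagnostic — downstream analyses
never use the diagonal). Pairs are streamed one ROI block at a time, so
memory is bounded by the largest ROI block, never the full cube-pair matrix;
each rotation is one BLAS cross-product of row-normalized cube banks.

## Network construction

Fisher's r-to-z (`atanh`) is applied after clipping |r| at 1 − 1e−7 so that
perfect correlations stay finite. Since `atanh` is strictly increasing,
thresholding r or z selects identical edge sets (tested).

Proportional thresholding retains the K = `round(s·n(n−1)/2)` largest
upper-triangle values at sparsity s and symmetrizes. Two conventions are
deliberate:

* **round, not floor**, for K — recorded in every run manifest;
* **deterministic tie-breaking** by descending value, then ascending
  (row, column). This makes repeated runs identical and makes edge sets
  *nested* across increasing sparsity levels even through ties.

The analysis grid is the seven levels 0.05–0.35 in steps of 0.05. Negative z
values are eligible edges (ranking is by value, not magnitude); at these
densities the cut always falls in the positive range for realistic
similarity matrices, but the convention is stated for completeness.

Thresholding is applied per subject (individual networks), never to a
group-average matrix: the whole point of the cube approach is
subject-level connectivity.

## Graph measures and their conventions

All measures are implemented from scratch (BFS distances, Brandes
dependency accumulation for betweenness, matrix triangle counting) and
validated against brute-force enumeration — matrix-power path counting and
neighbor-pair enumeration — on every connected graph with up to 6 nodes and
on seeded random graphs, plus an independent reference implementation
(igraph) in the test suite.

* **Degree (DC)**: row sums.
* **Clustering (CP)**: per node, 2·triangles/(k(k−1)); 0 when k < 2.
* **Betweenness (BC)**: unnormalized, each unordered pair counted once.
  Hub detection is rank-based, so normalization would not change hubs.
* **Path length (LP)**: networks at sparsity 0.05 are usually disconnected,
  and the analysis must not fall apart there. LP averages over *reachable*
  ordered pairs and the unreachable fraction is reported alongside; with no
  reachable pairs LP is missing. Global efficiency handles disconnection
  natively (1/∞ = 0).
* **Small-worldness (SW)**: (CP/CP_null)/(LP/LP_null) against
  degree-preserving null networks (double edge swaps, 10·edges attempted
  swaps, 20 nulls by default, seeded). When rewiring cannot change the graph
  (complete graph) the null equals the original and SW = 1. When no null
  network contains a single triangle while the observed network does, the
  ratio is unbounded and SW is reported as missing rather than infinite;
  group models then drop those subjects and report the count used.

## Stress scoring and group assignment

The 39-item life-event questionnaire is scored by counting events rated
negative (NLE count) and summing their ratings (negative total, ≤ 0).
Events never experienced are *absent*, not zero — the questionnaire asks
about events that happened. Cut-offs: at most 5 NLEs with total in [−5, 0]
is Low stress; 6 or more NLEs with total in [−20, −11] is High stress.
Everything else is `Unclassified` and excluded from group analyses — the
source cut-offs define only two strata and are silent about, e.g., 6+ NLEs
with a total of −10; a third explicit label is the least surprising
treatment. The assignment is purely window-based: it does not second-guess
whether a (count, total) pair is arithmetically attainable.

## Group inference

* **Hubs**: a node is a hub when its group-mean centrality exceeds the
  across-node mean by 2 SDs. The rule is applied per group and the tested
  set is the union — whether the original analysis pooled groups is
  ambiguous, and the union guarantees that a hub in *either* group is
  examined. Configurable via `n_sd`.
* **Global measures**: a linear model of the measure on group plus
  covariates (age, sex, site, pubertal development score, socio-economic
  status; sex and site dummy-coded). For a two-level factor this is exactly
  the ANCOVA F/t inference, and with no covariates it reduces algebraically
  to the pooled two-sample t-test (tested to 1e−12). Models are fitted both
  with and without SES, and both variants are reported.
* **Nodal tests**: two-tailed pooled t-tests at hub nodes for BC and DC and
  at *all* nodes for CP; the FDR family is all nodes tested for one metric
  at one sparsity level, corrected with step-up Benjamini–Hochberg
  (implemented directly; cross-checked against the stock implementation).
* **Partial correlations**: NLE count against each global measure,
  residualizing both on age, sex, site and z-standardized pubertal score —
  note this covariate set deliberately omits SES, mirroring the slightly
  different covariate choices of the two analyses it reproduces. A response
  fully explained by the covariates has a residual of floating-point dust
  with meaningless direction; the partial correlation is then 0 by
  convention.

Proportional thresholding fixes the edge count, so mean degree is identical
for every subject at a given sparsity; the group model on a constant
response is degenerate and reported as not estimable instead of a
spurious statistic.

## Edge statistics (NBS)

Edge-level inference runs on the *unthresholded* z matrices (connectivity
strength), not on binarized networks. The observed pooled-variance |t| per
edge is compared against random relabelings of subjects to groups (sizes
preserved, seeded, add-one convention: the observed labeling counts in its
own null, so p ≥ 1/(B+1) always). Two correction modes:

* `edge_fdr` (default): per-edge permutation p, then BH-FDR across edges.
  Default because the inference target is single edges.
* `component`: classic network-based statistics — edges above a primary |t|
  threshold form components whose edge count is compared to the permutation
  max-component null.

Covariates are not part of the permutation model by default; an optional
residualize-then-permute variant can be built from `partial_correlation`'s
residualization but is approximate and not wired into the default pipeline.

**A calibration limit worth knowing.** With B permutations the smallest
attainable p is 1/(B+1). After multiplicity correction over m edges, a
single-edge discovery at level α needs roughly B > m/α permutations; below
that, rejections require several edges to be simultaneously extreme and the
procedure becomes strongly conservative (empirically: far fewer than α of
null datasets show any significant edge). False-positive *control* is
therefore comfortably held, but exact α-level calibration of "any
discovery" is impossible at small B — which is why the production default
is thousands of permutations and the headline analyses use 10⁵.

## The synthetic world

The generator exists so that every downstream stage is testable without any
restricted data download. It states a world; it does not emulate a scanner:

* Each ROI has a fixed 27-value base texture ("motif"); each cube of a
  subject carries its ROI's motif plus independent Gaussian voxel noise
  (default SD 0.05 on a [0, 1] density scale), clipped to [0, 1].
* ROI pairs can share identical motifs (high similarity by construction),
  and High-group subjects have motifs at designated effect edges blended
  toward each other, raising similarity in expectation. The blend weight is
  0.15 per unit of `effect_size` (capped), so at the volume level
  `effect_size` is a *direction and magnitude knob*, not an exact Cohen's d
  — the mapping to the z-similarity scale runs through the noise and the
  rotation maximum. Where an exact standardized difference is required
  (power and calibration studies), `simulate_edge_dataset()` draws
  per-subject z matrices directly with an exact planted d.
* Questionnaire rows are constructed to land inside the intended group's
  cut-off windows (counts 0–5 with totals in [−5, 0], or 6–10 with totals in
  [−20, −11] clipped to attainability), so scoring round-trips to the
  intended group by construction — this validates the plumbing, not the
  questionnaire model.
* Covariates are simple conventions on plausible scales, not claims about
  any cohort: age ~ U[14, 15] years, sex ~ Bernoulli(0.5), two scanning
  sites, pubertal score ~ N(16, 2.7), socio-economic score ~ N(7, 3).
* One RNG stream per subject is derived from (master seed, subject index),
  so a cohort can be extended without reshuffling existing subjects.

What a green test therefore establishes: the algebra and conventions above,
determinism, error control under the stated noise model, and recovery of
planted effects. What it does not establish: behavior under scanner physics,
bias fields, segmentation error, nonlinear registration artifacts, or the
spatial autocorrelation structure of real cortex — none of which are
simulated.

## Numerical and engineering choices

* Clipping |r| at 1 − 1e−7 before `atanh` (finite z ≈ 8.4 for perfect
  correlation).
* Zero-variance cubes score 0; zero-variance edges in t-tests give t = 0
  when means agree and a capped sentinel (±1e12, flagged) when they do not.
* Seeds: every stochastic stage consumes a named substream derived from the
  master seed by an integer hash (range kept below 2³¹); no stage reads
  global RNG state, and library calls restore the caller's RNG.
* Volumes are NIfTI-1 (uncompressed `.nii`); the reader/writer is a minimal
  built-in implementation (no R NIfTI package is assumed), validated
  against an independent Python reader in the test suite. Matrices are TSV
  at 17 significant digits (lossless round trip); manifests are JSON and
  carry seeds, parameters and input hashes, never timestamps — reruns are
  bit-identical.

## Known limitations

* The atlas resizing assumes GM and atlas share a voxel grid; no
  resampling or nonlinear registration is provided (out of scope).
* Betweenness is computed in pure R; fine for the 10²-node parcellations it
  targets, not tuned for 10⁴-node voxel graphs.
* The edge-FDR permutation mode is conservative at small permutation counts
  (see above); component mode depends on an arbitrary primary threshold, as
  all classic NBS analyses do.
* Small-worldness at very low densities is frequently not estimable
  (triangle-free nulls); it is reported missing rather than extrapolated.
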
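---
title: "Multithreshold permutation inference for structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multithreshold permutation inference for structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connmtpc)
```

## The problem

Whole-brain tractography reduces each subject's white matter to a
symmetric matrix of streamline counts between atlas regions. Counts are
not comparable across subjects in absolute terms, and the near-universal
practice is to binarize: an edge exists when its count exceeds a threshold
τ. Every topological quantity computed downstream — density, efficiency,
clustering, betweenness, smallworldness — is then a function of τ, and
group differences can appear or vanish as τ moves. Low thresholds admit
false-positive edges; high thresholds amputate genuine weak connections.

This package implements inference that embraces the sweep rather than a
point choice: graph metrics are computed at every threshold, the group
test statistic becomes a *curve* over τ, and permutation of group labels
provides family-wise error control across the whole sweep. The same
machinery covers network-level metrics, node-level metrics (with
additional correction across regions), edge-level tests (network-based
statistics), and the topology of functional subnetworks.

## Data model and thresholding

A `stream_matrix` is a symmetric, zero-diagonal, nonnegative-integer
region×region matrix. Counts between a region pair are inherently
unordered, so asymmetric input is rejected outright rather than
symmetrized — an asymmetry signals an upstream bookkeeping error, not
noise.

Binarization is strict (`count > τ`), so τ = 0 means "any streamline at
all" and is a meaningful lowest threshold of the 0–20 sweep; an
`inclusive` flag flips to `≥` for compatibility with pipelines that use
the other convention. The 0–20 range is a soft bound: values above 20 work
but warn, since the count distribution's sparse tail makes high thresholds
unreliable.

Because global efficiency depends strongly on density, the package also
supports density-matched thresholding: keep the k highest-count edges,
k = round(d·n(n−1)/2), so all subjects sit at exactly the same density d
(grid 0.05–0.10 in steps of 0.005, the range of densities such connectomes
occupy mid-sweep). Ties in count are broken by ascending region index —
deterministic and independent of subject order. If a subject has fewer
than k nonzero edges the function keeps them all and warns with the
achieved density, rather than inventing edges.

## Graph metrics

All metrics operate on binary undirected graphs. Shortest paths,
betweenness counts, community detection and connected components are
delegated to igraph; the definitions and normalizations are fixed here:

* **Density** 2E/(n(n−1)); node-level analogue is degree.
* **Global efficiency** mean over ordered pairs of 1/d(i,j) with
  1/∞ = 0 (the Latora–Marchiori form). The phrase "inverse of the
  characteristic path length" is sometimes used loosely for this
  quantity, but the mean-of-inverse-distances form is what the Brain
  Connectivity Toolbox computes, handles disconnected graphs gracefully,
  and is adopted here; 1/PL is trivially available from
  `char_path_length()` if wanted.
* **Characteristic path length** mean geodesic distance over *reachable*
  pairs only (the BCT convention for disconnected graphs). With no
  reachable pair it is undefined (`NA` + warning).
* **Nodal efficiency** per-node mean of 1/d(node, j). Node-level
  "efficiency" is ambiguous in parts of the literature between this
  quantity and the Latora–Marchiori local efficiency (global efficiency of
  the neighbour subgraph). Nodal efficiency is the pipeline's node-level
  metric — it is the direct per-node decomposition of global efficiency —
  while the subgraph variant is provided separately as
  `local_efficiency_subgraph()` and not used by default.
* **Clustering** per node 2·triangles/(k(k−1)), zero for degree < 2.
* **Betweenness** endpoint-excluding geodesic betweenness normalized by
  (n−1)(n−2)/2 so the star centre scores exactly 1 and all values lie in
  [0,1].
* **Smallworldness** S = (C/C_rand)/(L/L_rand). Both references are
  analytic, not simulated: C_rand = ⟨k⟩/(n−1) (the clustering of a random
  graph equals its edge density) and L_rand = (ln n − γ)/ln⟨k⟩ + ½, the
  Fronczak closed form with γ ≈ 0.5772 the Euler–Mascheroni constant. At
  n = 100, ⟨k⟩ = 10 this gives L_rand ≈ 2.2493. The formula requires
  ⟨k⟩ > 1; below that S is undefined and reported as missing. Analytic
  references make S deterministic and cheap; the cost is mild bias at
  small n or near-threshold ⟨k⟩, which is why the sanity check uses
  n = 200 Erdős–Rényi graphs (mean S within 1 ± 0.1).
* **Modularity** Newman's Q maximized by deterministic greedy
  agglomeration (`igraph::cluster_fast_greedy`), returned with its
  partition. Greedy maximization is a lower bound on the optimal Q; since
  only the bound [0,1] and reproducibility matter downstream, a
  deterministic method is preferred over stochastic optimizers.

Every metric is verified in the test suite against brute-force oracles
(Floyd–Warshall distances, explicit triangle counting, exhaustive
enumeration of geodesics) on hundreds of random graphs with n ≤ 6.

## The ANCOVA and the permutation scheme

Groups are compared metric-by-metric with a one-way ANCOVA: the F (1
numerator df) for the group factor in
`value ~ group + age + gender + handedness`, computed as the
extra-sum-of-squares F of adding group to the covariate-only model.
Handedness (right/left/no-dominant-hand) enters as two indicators against
the right-handed reference; covariate columns that are constant in a given
sample are dropped, and genuinely collinear designs are an error naming
the offending column. Because the group factor adds a single column, the F
reduces to the regression of covariate-residualized values on the
covariate-residualized group indicator — one QR decomposition serves every
threshold, node, edge and permutation, which is what makes the permutation
loops cheap. The post-hoc t is the same model's group coefficient; its
square equals the F (checked to 10⁻⁹ in the tests) and its sign gives the
direction (PE minus control).

Permutations shuffle the raw group labels while covariates stay fixed —
the direct reading of "permute the group assignments". This is exact when
covariates are balanced between groups and is the scheme the correction
was described with; residual-based schemes (Freedman–Lane) are a known
alternative but are deliberately not the default, to keep the procedure
identical to its published form. The same permutation matrix is used at
every threshold (and node), which is what makes the max-statistic valid.

## MTPC: the decision rule

For a metric curve over thresholds τ₁ < … < τ_T:

1. observed F_t at every usable threshold (thresholds where the metric is
   undefined for any subject, or constant across subjects, are dropped
   with a warning — never imputed);
2. n permutations (default 500, seeded) give null curves F*_t;
3. the null distribution of max_t F*_t yields the critical value F_crit as
   its empirical (1−α) type-7 quantile (deterministic, interpolated);
4. contiguous runs of observed F_t > F_crit form clusters, scored by the
   trapezoid AUC of (F − F_crit) over τ within the cluster; a single-point
   cluster contributes (F − F_crit)·Δτ with Δτ the median grid spacing.
   Integrating the *excess* above the critical line makes the score vanish
   continuously at the cluster boundary, so single-point clusters are
   well defined;
5. the critical AUC A_crit is the mean over *all* permutations of each
   permutation's maximal supra-critical cluster AUC, counting 0 for
   permutations with no supra-critical excursion;
6. reject when the largest observed cluster AUC exceeds A_crit. The
   corrected p-value is the add-one estimator
   (1 + #{null max ≥ F_MTPC})/(n+1), never exactly zero.

Step 5 is the one point where the procedure's description admits two
readings: averaging over only the permutations that have a supra-critical
cluster, or over all of them. The first makes A_crit the conditional mean
of an already-extreme quantity: the observed curve then has to beat the
average of the top ~α tail, and simulation shows the realized family-wise
error drops to roughly α/3 (≈0.015–0.025 at α = 0.05). Averaging over all
permutations keeps the AUC criterion as a genuine secondary filter while
preserving calibration (realized FWER 0.045–0.055 across seeds in the
package's null simulations), so that is the implemented rule. The
acceptance suite pins this: on 200 null synthetic cohorts the rejection
rate must lie inside the exact binomial 95% interval around 0.05.

Node-level metrics add a second multiplicity: the null maximum is taken
across nodes as well as thresholds, giving one shared F_crit and A_crit
against which every region's clusters are evaluated. With a single node
this reduces exactly to the global procedure (asserted in the tests), and
the shared critical value is necessarily at least as large as any
single-node one.

## NBS

Edge-level inference follows the standard extent-based network-based
statistic: per-edge ANCOVA F on the raw streamline counts (weights, not
binarized edges — the conventional choice for NBS; a log1p option exists
for variance stabilization), supra-threshold graph at F > 3.1, connected
components scored by edge count, and a family-wise p per component from
the permutation distribution of the maximal component size (default
2,500 permutations). Edges nonzero in fewer than two subjects of either
group, or with zero variance, are excluded as degenerate. The intensity
variant (summing F over the component) is out of scope.

## Subnetworks

Functional subnetworks arrive as volumetric z-maps voxel-aligned to the
atlas label volume (registration is upstream). A region joins a
subnetwork when at least 50% of its voxels (inclusive, "50% or more")
exceed z = 4. The default-mode network is derived by weighting each map
by its mean value over the posterior cingulate region, summing the
weighted maps, and masking the sum the same way. The rich-club node set
ships as an editable plain-text list (bilateral superior frontal and
superior parietal cortices, precuneus, hippocampus, putamen, thalamus).
Exclusion of physiological-noise modes from a map set is a configuration
concern — subnetwork lists are user-supplied inputs, not hard-coded.

Each subnetwork analysis induces the subject-wise submatrices, recomputes
network-level metric curves and runs MTPC. Inducing commutes with
binarization (tested), so it does not matter at which stage the subnetwork
is cut out. Both density/efficiency and clustering/betweenness are
computed for every subnetwork, so either a density-style or an
efficiency-style reading of a subnetwork effect is covered.

## Synthetic cohorts: what they emulate, and what they do not

The generator produces two groups (defaults 123 and 125 subjects) of
116-region matrices with:

* a modular block structure (6 modules; within-module edge probability
  0.35, between-module 0.08) — the minimal topology that yields
  non-trivial clustering and modularity;
* heavy-tailed counts on existing edges,
  1 + NegBin(mean 14, size 1): with these defaults the 0–20 threshold
  sweep spans densities from ≈0.12 (τ = 0) through ≈0.06 (τ = 10) to
  ≈0.03 (τ = 20), bracketing the 0.05–0.10 density-matched grid in the
  mid-sweep the way real connectomes do;
* a group effect expressed as a multiplicative reduction of edge
  probability in the PE group — `effect_density = 0.2` means PE edges
  form with 0.8× the control probability — optionally confined to edges
  incident to a chosen node set;
* covariates sampled identically in both groups (age ≈ N(20.07, 0.25),
  65% female, handedness 74/7/19% right/left/none, matching a young
  population cohort); covariate slopes on edge probability default to
  zero so calibration and power studies isolate the group factor.

Passing tests on these cohorts shows the *inference machinery* is
calibrated and sensitive under a known generative model. It does not show
that real tractography counts follow a negative binomial, that real
effects are multiplicative on edge probability, or that real covariates
are balanced — the generator makes no claim to reproduce any particular
cohort's metric values.

## Numerical choices and degenerate inputs

* Empirical quantiles: type 7 everywhere (deterministic, interpolated).
* Permutation p-values: add-one estimator, so p ∈ (0, 1].
* Response columns with (numerically) zero residual variance are treated
  as constant and yield F = 0 at the ANCOVA level or are dropped at the
  curve level; near-zero variance is caught with a relative tolerance so
  floating-point dust does not produce spurious huge F values.
* Disconnected graphs: distances are ∞, efficiency terms contribute 0,
  path length averages reachable pairs, and a graph with no reachable
  pair has undefined path length.
* Mean degree ≤ 1 leaves the analytic L_rand undefined; smallworldness is
  reported missing at such thresholds and those thresholds drop out of
  its curve.
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state. The pipeline derives per-stage seeds from one master
  seed via a fixed integer scheme, so a module rerun with the derived seed
  reproduces the pipeline's numbers exactly — this is asserted in the
  tests, as is byte-identical report JSON across reruns.

## Problem sizes used in validation

The calibration and power studies are sized to be decisive yet quick:
family-wise error uses 200 null cohorts of 20 subjects per group, 10
regions, 5 thresholds and 200 permutations; power uses 50 replicates of 40
per group (20 regions) for MTPC and 20 per group (12 regions, a planted
6-edge clique with +20 counts) for NBS; the metric oracle suite uses 500
random graphs with n ≤ 6, where exhaustive path enumeration is exact.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted bounds (e.g. ±0.015 on a 0.05 rejection rate) while keeping the
whole suite in the minutes range.

## Known limitations

* Binary, undirected graphs only: no FA- or count-weighted metric
  variants, no directed measures, no rich-club coefficient curves.
* MTPC assumes the same threshold grid for all subjects; subjects are
  never dropped per-threshold, the threshold is.
* The permutation scheme assumes exchangeability of subjects under the
  null; strong group imbalance in covariates would call for the
  (implemented but non-default) residual-based alternative.
* Greedy modularity is a lower bound on optimal Q.
* NBS component extent is the only component statistic.
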
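---
title: "Morphometric similarity networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscortex)
```

## The analysis in one paragraph

A morphometric similarity (MS) network treats each cortical region as a
node described by a vector of MRI-derived morphometric features — here ten
of them: surface area, gray matter volume, mean and SD of cortical
thickness, Gaussian and mean curvature, folding and curvature indices, and
mean fractional anisotropy and mean diffusivity of cortical gray matter.
Within each subject, every feature is z-scored across regions and every
pair of regions is correlated (Pearson, across the ten features), giving
one symmetric region-by-region MS matrix per subject. Case–control
inference then proceeds at three levels: node summaries (regional mean MS
and its average within functional and cytoarchitectonic subnetworks),
individual connections (the network-based statistic, NBS), and graph
topology (efficiency, modularity, transitivity and nodal centralities of
binarized graphs across a sparsity range). All group comparisons adjust
for age, sex and their interaction and control the false discovery rate by
Benjamini–Hochberg within pre-declared families. Multi-site feature tables
are harmonized beforehand with an empirical-Bayes location/scale model.

## The synthetic cohort: what it emulates and what it does not

The package replaces MRI-derived inputs with a generator
(`generate_cohort()`) whose latent structure was designed — and then
frozen — to reproduce the statistical features of real cortical MS data
that the downstream analysis depends on:

* **A smooth similarity gradient.** Regions sit on a ring; their latent
  profiles vary smoothly along it (four harmonics with 1/k loading decay).
  Nearby regions are strongly similar, so binarized graphs are clustered,
  connected down to low sparsity, and small-world — the regime the
  threshold-selection rule assumes.
* **A skewed hubness field.** A smooth "hubness" loading multiplies a
  global feature pattern: most regions sit on a positive plateau and a
  contiguous minority arc (a limbic/insular-like territory) is strongly
  anti-correlated with the rest. After the within-subject z-scoring this
  yields what real MS matrices show: a near-zero matrix-wide mean MS with
  regional means spanning roughly −0.07 to +0.05, most regions slightly
  positive and hub-like, a minority negative. A matrix-wide mean MS of,
  say, +0.3 is not attainable at all: z-scoring forces each feature column
  to sum to zero, which caps the average off-diagonal covariance at zero.
  What sparsity thresholding actually needs is a wide, non-degenerate
  weight distribution, which this structure provides.
* **Stable region identities with homogeneous reliability.** Region
  idiosyncrasies (0.2 SD) are shared across subjects; subject noise
  (0.3 SD) is not. Both noise components are drawn with a fixed per-region
  norm and the latent signal rows are normalized to a common power, so no
  region's whole correlation row is attenuated by an unlucky draw — the
  empirical analogue is that measurement reliability varies little across
  cortex. Without this, isolated nodes at low sparsity are dominated by
  noise-tail artifacts rather than topology.
* **Gaussian pooled marginals.** Each feature column is rank-gaussianized
  within subject before being mapped to realistic feature scales, so the
  pooled distribution of any feature is Gaussian by construction even
  though the hubness field is skewed. This mirrors the common practice of
  normalizing raw morphometry and keeps the generator's marginals free of
  structural skew.
* **Covariates.** Ages and sex ratios follow the demographic profile of a
  four-site case–control cohort (controls 33.3 ± 10.0 years, 59% male;
  patients 34.2 ± 10.0 years, 66% male; site sizes proportional to the
  four-site layout). Illness duration is generated as
  `age − onset + noise`, deliberately reproducing the strong
  age–duration collinearity that undermines clinical association analyses;
  antipsychotic dose is missing for a quarter of patients.
* **Site effects** are per-feature location shifts and scale factors,
  constant across regions — exactly the additive/multiplicative model the
  harmonization assumes. A consequence worth knowing: because MS
  construction z-scores features within subject, per-feature affine site
  effects cancel in the MS matrices themselves; harmonization matters on
  the raw feature scale.

The disease effect (`implant_group_effect()`) mixes each target region's
feature vector with standardized noise, `v' = (1 − λ)v + λε`, for patient
subjects only. This attenuates the region's correlation with the rest of
the cortex by a factor `(1 − λ)/√((1 − λ)² + λ²)` — a focal loss of
morphometric identity. At λ = 1 the region's expected MS is zero. Because
the mean-MS consequence of decorrelation is proportional to the region's
baseline mean MS, effects implanted in high-|mean-MS| regions (hubs or the
anti-correlated arc) are the detectable ones; effects in regions whose
baseline mean MS is near zero surface in the edge-level (NBS) and
topology-level analyses instead. A generated cohort is bit-identical given
its configuration, including the seed.

What a green test on this cohort does **not** establish: that the pipeline
recovers effects under realistic segmentation error, site-by-disease
interactions, non-affine scanner effects, motion artifacts, or feature
distributions with real morphometric skew. The generator makes the
*statistical geometry* of MS data available at desk scale, not its
physics.

## Harmonization

`fit_combat()`/`apply_combat()` implement the canonical parametric
empirical-Bayes location/scale model: per (region, feature) target,
`y = α + Xβ + γ_site + δ_site ε`, with least-squares standardization
preserving the declared covariates (age, sex, group), a normal prior on
site locations γ and an inverse-gamma prior on site scales δ², both
estimated by moments and shrunk by fixed-point iteration (tolerance 1e-4,
maximum 100 iterations). One property deserves emphasis: EB shrinkage
pulls each target's location estimate toward the site mean, so when the
true site effect is *uniform* across targets the per-target residue after
harmonization is about half the sampling noise of the site means — around
0.1 units at 100 subjects per site. The site-*common* shift is removed
essentially exactly. Validation therefore checks the aggregate site gap,
the between-site variance ratio, covariate preservation, and idempotence
(re-fitting harmonized data finds site effects ≈ 0), not exact per-target
alignment, which no EB method delivers.

## Network-based statistic

Edge-wise inference uses OLS of each edge weight on
`[intercept, group, age, sex, age×sex]` (group coded patient = 1, so
negative t means weaker in patients), one-sided per direction, thresholded
at `alpha / n_edges` (Bonferroni over the connection universe; with 308
regions and the conventionally printed universe of 47,228 connections this
is the familiar 0.0000011 — the computed C(308,2) = 47,278 rounds to the
same 7 decimals, and the universe is configurable). Supra-threshold edges
are grouped into connected components and each component's extent is
referred to a permutation null of the maximum extent, with the add-one
correction `(1 + #{null ≥ obs})/(1 + B)`.

The permutation scheme matters more than is usually acknowledged. The
default permutes **whole subject rows** and recomputes a
partial-correlation pivot, `r = u'M_Z y / ‖M_Z y‖` with `u` the unit-norm
nuisance residual of the group regressor: the observed statistic is
exactly the identity permutation of the same formula, so observed and null
statistics are symmetric by construction, and the scheme is exact whenever
subjects are exchangeable under the null. Freedman–Lane residual
permutation is available (`perm_scheme = "freedman_lane"`), but measured
calibration on correlated-edge data shows it mildly liberal (≈0.07 at
nominal 0.05): residualizing against the nuisance model couples subject
rows, and the highly nonlinear max-component statistic amplifies the
approximation. Simple label permutation is also available. A second
practical point: the max-extent statistic is integer-valued, and near or
below the percolation threshold of the supra-threshold graph its null
distribution is heavily tied, which makes the permutation p conservative —
calibration experiments should use a primary threshold dense enough that
extents behave continuously.

## Graph construction and measures

Binarization keeps the top `floor(s·C(N,2))` edges by signed weight (most
similar pairs first; ranking by absolute value is available but not the
default, since strongly negative MS means dissimilarity, not connection
strength), with deterministic lexicographic tie-breaks. The analysis
range is chosen by the construction rule applied literally per subject and
threshold: the graph must be connected (else the small-worldness scalar is
not estimable) and its small-worldness scalar
`σ = (C/C_rand)/(L/L_rand)` must exceed 1.1, with C transitivity-based
clustering, L the characteristic path length, and the reference values
averaged over 20 Maslov–Sneppen degree-preserving rewired surrogates (10
swap attempts per edge; surrogate path lengths average over reachable
pairs so an occasionally disconnected surrogate stays finite). The longest
contiguous qualifying run of thresholds is retained. Note that
connectivity at a given sparsity is scale-dependent — mean degree is
`s(N − 1)` — so the familiar 0.10–0.40 range is a property of ~300-region
parcellations, not of miniature demonstrations.

Global measures are global efficiency, local efficiency, Louvain
modularity (fixed seed; the reported Q is the Newman modularity of the
partition found) and transitivity; nodal measures are degree,
unnormalized betweenness centrality, eigenvector centrality (leading
eigenvector of the largest component, non-negative, unit Euclidean norm,
zero off-component) and nodal efficiency. Measures are averaged,
unweighted, over the selected thresholds before group comparison. All
shortest-path measures are property-tested against Floyd–Warshall and
path-counting oracles on random graphs.

## Inference families

Group comparisons are OLS with `[group, age, sex, age×sex]`; "their
interaction" is read as age-by-sex (the group-by-covariate readings are
selectable by building the design by hand). BH-FDR is applied once per
declared family — regions (N), subnetworks (14), global measures (4),
nodal measures (4N) — at q < 0.05. Degenerate covariates (constant age or
single-sex cohorts) are dropped so the model reduces cleanly to the pooled
two-sample t. Clinical associations are Spearman correlations of the
units that survived group comparison, computed within the patient group
for illness duration, symptom scores and dose, and within each group for
cognition, corrected per clinical variable, with pairwise-complete
handling of missing values. The age-adjusted variant is a rank-based
partial correlation (residualize the ranks of both variables on the ranks
of age); with ~200 subjects its standard error is ≈ 0.07, which is worth
remembering when interpreting "the association disappeared after age
adjustment".

## Numerical conventions and degenerate inputs

Sample (n − 1) standard deviations throughout; MS diagonals stored as 0
and excluded from every summary; zero-variance feature columns and
zero-variance region rows are errors (zero-variance harmonization targets
are errors by default, pass-through by flag); single-site harmonization is
the identity with a warning; sites unseen at fit time are errors; a
permutation seed is required for every NBS run and fully determines the
result; edge enumeration is upper-triangle lexicographic everywhere, which
fixes sparsity tie-breaks and makes serialized outputs byte-stable across
runs.

## Known limitations

* The generator's ring geometry is a one-dimensional caricature of
  cortical topology; it produces the right edge-weight and hubness
  statistics but not realistic community structure beyond the
  gradient-plus-arc pattern.
* Canonical EB harmonization leaves per-target residues of order half the
  site-mean sampling noise when site effects are uniform across targets
  (see above); pipelines needing exact per-target alignment should use
  fixed-effects centering instead.
* NBS calibration was verified for the whole-row permutation scheme on
  this generator's data class; Freedman–Lane remains available but is
  measurably liberal under strong inter-edge correlation.
* The threshold-selection rule is evaluated per subject and per threshold
  literally; with very small subject counts a single noisy subject
  truncates the range.
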
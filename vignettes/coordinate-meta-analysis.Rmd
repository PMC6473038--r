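---
title: "Coordinate-based meta-analysis of activation foci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based meta-analysis of activation foci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focimeta)
```

## The problem

Functional imaging studies of action awareness (and of most cognitive
domains) report their results as *activation foci*: peak coordinates in a
stereotactic space, a handful per contrast. Any single study is noisy and
underpowered, so the questions that matter — do motor intention and the
sense of self-agency recruit separable parts of the mesial frontal wall? —
are asked of the literature as a whole. `focimeta` implements a desk-scale,
fully scripted version of that workflow: spatial clustering of pooled foci,
per-cluster inference about which experimental construct the cluster
belongs to, activation-likelihood (ALE) conjunction mapping, and a
confirmatory seed-based resting-state connectivity stage, together with
seeded synthetic-data generators so every stage can be exercised and
calibrated against planted ground truth.

## Data model and coordinate spaces

A `foci_dataset` is an ordered table of peaks: study id, contrast id, class
label, and an (x, y, z) coordinate in MNI millimetres. Ingestion normalises
everything to MNI: rows tagged Talairach are mapped through the inverse of
the standard piecewise-linear MNI-to-Talairach ("Brett") transform — two
pure linear maps, one above and one below the axial plane, with no
translation term. The inverse selects the half-space by the sign of the
*output* (MNI) z; because the reconstructed z has the same sign under either
inverse, the round trip is exact to machine precision everywhere, including
on the z = 0 plane (which resolves to the superior map on both legs).
Duplicate peaks are retained: the analyses treat peaks as exchangeable
units, and no principled deduplication rule exists at this layer. Rows whose
coordinates fail to parse are rejected into a per-row ingestion log rather
than silently dropped or fatal.

The per-label *priors* of a dataset are its exact class proportions
(`dataset_priors()`); with 246 intention and 96 self-agency peaks out of
342 these are 0.7193 and 0.2807. They are the success probabilities for the
composition tests below, which is why they are computed as exact rationals
rather than rounded.

## Ward clustering with a spatial-resolution cut

Foci are clustered agglomeratively under Ward's minimum-variance criterion:
the cost of merging clusters A and B is the increase in within-cluster sum
of squared deviations,

$$\Delta(A,B) \;=\; \frac{|A||B|}{|A|+|B|}\;\lVert c_A - c_B\rVert^2 ,$$

evaluated directly from cluster sizes and centroids. Equal-cost ties break
to the lexicographically smallest pair of cluster indices in input order, so
the merge sequence is a deterministic function of the input. Ward linkage is
reducible, so merge costs are monotone non-decreasing, and the tests verify
the whole sequence against a brute-force oracle that recomputes every
pairwise ESS increase from raw member coordinates, as well as against
`stats::hclust(method = "ward.D")` on squared distances (whose heights are
exactly twice this cost).

The dendrogram is cut by a *spatial resolution* rather than by a cluster
count: `cut_at_resolution()` returns the coarsest partition whose mean
per-cluster standard deviation is at or below the resolution (default 5 mm)
on each axis separately. Standard deviations use the sample (n − 1)
denominator and are defined as 0 for singletons, which are included in the
mean; the 4–5 mm mean spreads this produces sit naturally just under the
5-mm ceiling. Two genuinely open readings of "maximum mean spatial variance
within each cluster in the three directions" exist; we adopt the mean-over-
clusters reading because that is the statistic reported alongside such
analyses (mean per-axis sd), and expose the stricter per-cluster-maximum
variant behind `criterion = "max"`. The cut respects dendrogram structure
only — no post-hoc reassignment — and is therefore nested: coarsening the
resolution can never increase the number of clusters.

## Cluster-composition inference

Given the cut, each cluster is asked: is one class over-represented here
relative to its share of the whole dataset? For label $\ell$ with prior
$p_\ell$, observed count $x$ in a cluster of $n$, the test statistic is the
one-sided exact binomial tail

$$P(X \ge x), \qquad X \sim \mathrm{Binomial}(n,\, p_\ell),$$

computed by direct summation of log-scale terms (`binomial_tail()`). The
convention is deliberately one-sided (enrichment): an all-intention cluster
of ten foci under the 0.7193 prior gives 0.037 (printed as 0.04), and a
4-of-5 self-agency cluster under 0.2807 gives 0.024 (printed as 0.02) —
values a two-sided convention cannot produce. The null hypothesis is
equality with the prior. A cluster is tagged enriched for the label with
the smallest tail when that tail is ≤ α (default 0.05) and the minimum is
unique; exact ties stay unclassified. P-values are reported per cluster
without multiplicity correction, matching the per-cluster reporting
convention of this literature; a Benjamini–Hochberg option
(`adjust = "BH"`) is available and can only remove tags. The exact test is
conservative at small n, so its type-I rate at the prior sits below the
nominal level — the suite checks this by simulation.

## ALE maps, nulls, and conjunction

The modelled-activation (MA) map of one experiment places an isotropic 3-D
Gaussian at each focus, scaled as a probability density integrated per voxel
(value = density × voxel volume, hence in [0, 1)). Within an experiment
kernels combine **non-additively** — the voxel takes the *maximum* over the
experiment's focus kernels — so many nearby peaks from a single experiment
cannot out-vote the rest of the literature. Across experiments the ALE map
is the probabilistic union $1 - \prod_i (1 - \mathrm{MA}_i)$. The kernel
FWHM defaults to 10 mm; the width is an explicit, documented parameter
(sample-size-dependent kernels are out of scope), and the kernel is
truncated at 4σ.

Significance is assessed against a Monte-Carlo spatial-randomisation null:
each iteration relocates every experiment's foci uniformly within the mask
(uniform over mask voxels with within-voxel jitter), recomputes ALE, and
pools all in-mask voxel values into a 4096-bin histogram. Empirical upper
tails are evaluated conservatively at bin resolution. This replaces the
analytic permutation histogram of the reference desktop tools with a
transparent, seed-controlled equivalent; it is validated by its own
calibration properties (reproducibility given the seed, stability of the
95th percentile under doubling of iterations, false-positive control of the
downstream FDR step), not against any external implementation.

Thresholding follows the meta-analytic convention: per-dataset p < 0.05
uncorrected pre-thresholds each input ALE map, the conjunction image is the
voxel-wise **minimum** of the thresholded maps, and FDR (Benjamini–Hochberg
under positive dependence, "pID", q = 0.05) plus a cluster-extent rule
(components of volume strictly exceeding 300 mm³, 26-connectivity) are
applied to the conjunction against a null that relocates *both* designs and
pools the voxel-wise minimum. Whether the minimum is taken before or after
thresholding is not fully determined by the workflow we model; both orders
are implemented (`order = "threshold_first"`, the default, or
`"min_first"`). Surviving clusters are reported with volume, ALE-weighted
centre of mass and peak value/location. For single-class datasets, where no
composition test exists, clusters of the 5-mm cut are instead
cross-validated by intersection: a cluster is retained when a surviving ALE
voxel lies within the clustering resolution of its centroid.

The default grid is 2 mm isotropic over the MNI bounding box
[−90, 90] × [−126, 90] × [−72, 108] mm with an all-inclusive mask (a
user-supplied NIfTI mask can replace it); the analysis drivers and tests
run on 4–8 mm grids, which exercise identical code paths at desk scale.

## Seed-based resting-state connectivity

The confirmatory stage takes two seed regions — spheres of 5 mm radius (the
clustering resolution) centred on cluster centroids, since the upstream
analysis defines clusters only by centroid and spread — and computes, per
subject, the Pearson correlation between the seed's mean time course and
every voxel, Fisher-z transformed (clipped at |z| ≤ 18 so r = ±1 voxels
stay finite; constant voxels are defined to have r = 0). At the second
level the two seeds' z maps are compared by a voxel-wise paired t-test.
Cluster-level FWE correction uses **sign-flip permutation** of whole-subject
difference maps: clusters form at one-sided voxel p < 0.001 and survive if
their size exceeds the 95th percentile of the permuted maximum-cluster-size
null. Sign flipping is exact for the paired design under exchangeability of
the difference sign, and replaces random-field-theory smoothness estimation,
which belongs to the toolchain we do not model. The conjunction of the two
simple effects is the voxel-wise minimum of the one-sample t maps, masked to
voxels surviving both corrected simple-effect maps — the conservative
minimum-statistic reading.

Preprocessing (realignment, filtering, nuisance regression, smoothing) is
out of scope by design: synthetic runs are generated *post-preprocessing*
as white Gaussian series with planted correlation structure.

## Synthetic data: what it emulates and what it does not

`generate_foci()` draws each planted blob from axis-aligned Gaussians
(matching the per-axis sd reporting convention), assigns the blob's class to
all of its foci, scatters background foci uniformly in a brain-sized box
with the *remaining* label pool randomly interleaved — so per-class totals
are exact by construction — and assigns study ids round-robin. The default
design (`aa_foci_design()`) mirrors the published study conditions: 342
foci, exactly 246 intention / 96 self-agency, nine pure blobs (five
intention of sizes 10/17/9/9/13, four self-agency of sizes 5/7/5/5 — the
printed sizes of the nine significant clusters) at plausible well-separated
MNI sites, per-axis sd 4.5 mm, 262 uniform background foci, 31 studies.
`generate_bold()` plants regions whose series are
$\rho\,s + \sqrt{1-\rho^2}\,\varepsilon$ around a shared unit-variance seed
course; defaults follow the resting-state design (32 subjects, 202 retained
volumes, ρ = 0.6). Both generators are bit-reproducible given seeds.

What the synthetic data does **not** emulate: inter-study heterogeneity in
peak density, anatomically structured (grey-matter-shaped) background,
autocorrelated or physiologically structured BOLD noise, motion, and
smoothness-induced spatial correlation in the noise. Passing recovery tests
therefore demonstrates correctness of the pipeline's statistics under its
stated assumptions, not performance on real data.

A consequence worth stating plainly: with a uniform 262-focus background,
the 5-mm mean-sd cut lands near 110 clusters (uniform background is far more
diffuse than real foci, which concentrate in grey matter), intention blobs
frequently absorb a background focus or two — and a single admixed
self-agency focus in a 13-focus cluster already lifts the one-sided tail to
0.084 — while small all-self-agency background clusters (3–5 foci) reach
tails of 0.002–0.022 at a rate of a few per dataset. *Perfect* recovery
(every planted blob flagged, zero background flags) is therefore not an
achievable operating point of the exact test at α = 0.05 under these
conditions, and the suite instead verifies the achievable properties: flags
concentrate overwhelmingly on planted structure, the pure self-agency blobs
are repeatedly rediscovered within the analysis grain, and the anchor
P-values of the composition convention are reproduced exactly. The strict
joint-recovery criterion is retained in the acceptance suite at full
strength, where it documents this limit rather than being weakened to pass.

## Numerical choices and degenerate inputs

* Binomial tails sum log-scale terms from the largest term; agreement with
  `pbinom` and with exhaustive outcome enumeration is tested to 1e-10.
* Ward tie-breaks are lexicographic in input order; the all-singleton
  partition guarantees the resolution cut always exists; zero-spread
  (duplicate) points are legal and collapse to one zero-sd cluster.
* ALE values are capped below 1; unions are computed via `log1p` to keep
  precision when many small MA values combine.
* Empirical p-values are conservative at histogram-bin resolution; an
  all-zero observed map yields p = 1 everywhere and an empty (not
  erroneous) result.
* Components use 26-connectivity by default; "exceeding" a volume threshold
  is strict (a 296 mm³ component dies at 300 mm³, a 304 mm³ one survives).
* The paired t statistic at zero-variance voxels is defined as 0 (zero
  mean) or ±Inf (non-zero mean), which the permutation machinery handles.
* Problem sizes in the drivers and tests — 4–8 mm grids, 100–500
  Monte-Carlo/permutation iterations, 8–32 subjects — were chosen as the
  smallest sizes at which the statistical properties under test are stable;
  all code paths are size-independent.

## Known limitations

* The ALE null pools voxels and histogram bins; extremely small p-values
  are bounded by 1/(iterations × mask size) and bin width.
* The empirical kernel widths used by reference desktop ALE tools (derived
  from per-experiment sample sizes) are intentionally not modelled; the
  fixed-FWHM kernel makes the non-additive algebra exact and testable.
* The composition test treats peaks as exchangeable across studies; between-
  study dependence of foci is not modelled, in either direction.
* Cluster validation by map intersection uses centroid-to-voxel distance,
  not full cluster extent; a very elongated cluster could be validated by a
  hotspot near its centroid but far from most of its mass.
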
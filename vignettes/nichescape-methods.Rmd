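---
title: "Methods: spatial niches, co-localization and malignancy calling"
author: "nichescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial niches, co-localization and malignancy calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichescape)
```

# Scope and data model

nichescape packages the spatial statistics used to dissect the tumor
microenvironment in spot-based spatial transcriptomics (Visium-style data,
as in non-small-cell lung cancer cohorts profiled before and after
immunochemotherapy): composition-cluster ("niche") analysis of deconvolved
cell-type weights, probabilistic cell-type co-occurrence, a Ripley cross-K/L
co-localization suite with Monte-Carlo envelopes, a CNV-similarity
malignant-cell classifier, and per-spot signature scoring. Upstream steps —
QC, clustering, deconvolution (e.g. RCTD), CNV inference (e.g. inferCNV) —
are out of scope; their *outputs* are this package's inputs.

All spatial statistics treat spots as points at their centers. A
`SpotGrid` carries barcodes, array indices, full-resolution pixel
coordinates, one micron-per-pixel scale, and a rectangular observation
window; every public distance is in micrometers. The window is the bounding
box of the spot centers padded by half the median nearest-neighbor spacing,
so each spot owns roughly half a lattice cell of margin. A convex hull
would hug the tissue more tightly, but the padded box is deterministic and
cheap, and because every Monte-Carlo null below is simulated on the *same*
window and lattice as the observed pattern, window-induced bias cancels in
the comparison.

One geometric note: the platform's spot diameter is 55 µm with a stated
10 µm gap, suggesting a 65 µm center-to-center pitch, while the nominal
array pitch is 100 µm. Because the two figures cannot both hold, the pitch
is a configurable parameter (`pitchUm`, default 100 µm for synthetic
lattices) rather than a constant, and it only affects the synthetic
generator and the default r-grid origin — the estimators read geometry from
the data.

# Niche (composition-cluster) analysis

Spots are clustered by k-means on the raw deconvolution weight rows
(squared-Euclidean objective, `nInit = 10` restarts keeping the lowest
within-cluster sum of squares). Weights are deliberately *not* z-scored:
rows are compositions on a common scale, and per-type scaling would inflate
the noise of rare cell types. Labels are relabeled by decreasing cluster
size (exact ties broken by centroid composition) so results are
deterministic and invariant to row order.

Three criteria choose the number of niches over a candidate range:

* **Calinski-Harabasz**: $CH(k) = \frac{B/(k-1)}{W/(n-k)}$ with $W$ the
  within- and $B$ the between-cluster sum of squares; vote = argmax.
* **Gap statistic**: $\mathrm{gap}(k) = \overline{\log W^{ref}_k} - \log W_k$
  over $B = 50$ reference datasets drawn uniformly over each type's
  observed range (the simplest published reference; adequate for
  compositions, which occupy a box-like region of the simplex). Reference
  fits use a single k-means start, as is conventional; the vote is the
  smallest $k$ with $\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - se(k+1)$,
  $se = sd \cdot \sqrt{1 + 1/B}$.
* **Elbow**: the $k$ whose point on the min-max-normalized WSS curve lies
  farthest from the chord joining the curve's endpoints.

The recommendation is the majority vote, ties resolved in favor of CH. In
the idealized zero-noise limit (every spot exactly at its niche mean, equal
niche sizes) the WSS curve of equidistant niche means is *linear* in $k$,
so the elbow criterion is uninformative there and votes for the smallest
candidate; CH and the gap statistic still identify the planted $k$, and the
majority rule recovers it. Candidate $k$ exceeding the number of distinct
compositions are skipped with a warning (the fit is undefined).

Co-occurrence within a niche follows the probabilistic (Veech-style) exact
approach. Presence of a type in a spot is binarized by the same quantile
rule used for positive-spot calling (weight strictly above the type's
within-niche 25th percentile) — the upstream tool's own binarization is not
fully specified, and reusing the co-localization rule keeps the two modules
consistent. Given marginals $(N, n_a, n_b)$ the joint count follows the
hypergeometric law; $p_{gt} = P(X \ge j_{obs})$ and $p_{lt} = P(X \le
j_{obs})$ classify a pair as positive ($p_{gt} < 0.05$), negative
($p_{lt} < 0.05$) or random. Types present everywhere or nowhere force
$p = 1$ and are flagged degenerate.

Niche prevalence across samples is summarized per sample (fractions of
spots per niche) and per group (spots pooled, i.e. samples weighted by spot
count), with a Kruskal-Wallis test per niche on the per-sample fractions.
The test is withheld (NA) when a group contributes fewer than two samples.

# Cross-type co-localization

**Positive spots.** A spot is positive for a type when its weight strictly
exceeds the type's 25th-percentile weight over the sample's spots
(linear-interpolation quantile; "exceeding" read as strict inequality). The
threshold is per sample by default. Samples with fewer than 40 positive
spots for either type are excluded — exactly 40 passes.

**Estimator.** For patterns $i, j$ on window $A$,
$$\hat K_{ij}(r) = \frac{|A|}{n_i n_j} \sum_{p \in i}\sum_{q \in j}
w(p, q)\, \mathbf 1[d(p,q) \le r],$$
with $w \equiv 1$ by default or Ripley's isotropic rectangle correction
(reciprocal of the fraction of the circle through $q$ centered at $p$ inside
$A$; valid for $r$ up to half the shorter side, which the r-grid respects).
$\hat L = \sqrt{\hat K/\pi}$ and $D(r) = \hat L(r) - r$, which is zero in
expectation under cross-type independence. A spot positive for both types
contributes a pair at distance zero; excluding coincident pairs would bias
against co-localization at the spot scale. The default r-grid is 30 equal
steps from half the lattice pitch to a quarter of the shorter window side.

**Null model and envelopes.** The null of "spatial independence between the
two cell types" is simulated on the sample's own lattice: each simulation
redraws each type's positive set as an independent uniform subset of the
spots, preserving $n_i$ and $n_j$ (`independent_relabeling`). This
conditions on the observed abundances and the tissue geometry — a
continuous CSR null would misstate both. A `label_swap` variant (redrawing
both sets from the union of observed positive spots) is available for
sensitivity analysis. Pointwise envelopes at level $1-\alpha$ discard the
$\lfloor \alpha(n_{sim}+1)/2 \rfloor$ most extreme simulated $D(r)$ per
tail (with 19 simulations at level 0.9 this keeps the second-smallest and
second-largest values). The global test uses $T = \overline{D(r)}$ with the
add-one convention $p = (1 + \#\{T_{sim} \ge T_{obs}\})/(n_{sim}+1)$, so
$p$ is never zero and is exactly uniform under the null.

**Effect sizes.** The Aggregation Index is the fraction of grid distances
with $D(r) > 0$ (a [0,1] measure of attraction breadth, invariant to
monotone transforms of positive $D$); Cohen's d is
$\overline{D}/sd(D)$ with the unbiased standard deviation, reported NA when
$sd(D) = 0$. Edge correction defaults to `none` because observed and
simulated patterns share the window, so the envelope comparison is
unbiased; `isotropic` is offered for descriptive K values. Default
simulation count is 999 with 95% envelopes.

# Malignant-cell classification from inferred CNV

Given a cells-by-bins matrix of inferred copy-number values centered at 1
(observations plus normal references), the classifier is:

1. **Aberration score** per cell: mean of $(v - 1)^2$ over bins — a mean,
   not a sum, so scores are comparable across bin counts.
2. **Reference-malignant set**: the $\lceil 0.05\,n_{obs} \rceil$
   top-scoring *observation* cells (ties at the cut broken by cell id, so
   the set is deterministic).
3. **Similarity**: Pearson correlation of every cell's profile with the
   element-wise mean profile of the reference set. The mean-profile form is
   cheaper than averaging pairwise correlations and ranks cells nearly
   identically. Flat profiles get similarity 0 with a degenerate flag.
4. **Call**: malignant iff similarity strictly exceeds 0.20 *and* ranks in
   the top 20% of similarity scores (the source procedure names both rules
   without stating their conjunction; AND is the default, and
   `threshold_only` / `top_frac_only` policies expose each alone). The
   ranking pool is *all* scored cells — observations and references — while
   reference cells are never eligible for the call itself. Ranking within
   observations alone would cap recall at the top fraction whenever most
   observation cells are genuinely malignant, which is exactly the regime
   the procedure targets.

The classifier is deterministic given the matrix and configuration. Its
accuracy claims are validated by planted-truth recovery (below), not by
reproducing any cohort's cell counts.

# Per-spot signature scoring and statistics

Gene sets are the top 25 significant markers per cell type by log fold
change (ties broken alphabetically). For synthetic end-to-end tests a
one-vs-rest Wilcoxon marker test is provided; real marker tables come from
the user's single-cell workflow.

The per-spot score is a rank-based single-sample enrichment statistic in
the ssGSEA spirit: genes are ranked within the spot (average ranks for
ties), in-set genes weighted by $\mathrm{rank}^{0.25}$, and the score is
the running difference between the in-set weighted cumulative distribution
and the out-set unweighted one, summed along the ranking. Two
normalizations depart from the classic form, deliberately: the in-set
cumulative mass is divided by its *expectation* under random set placement
(total rank-weight $\times |S|/N$) rather than the realized in-set weight,
and the analytic null expectation of the running difference is subtracted.
The classic ratio form has a strictly positive null mean (its weighted CDF
rises faster than the uniform CDF for any placement); the linearized,
centered form has *exactly* zero mean under permutation of expression
across genes, while preserving rank-invariance (any strictly increasing
per-spot transform — `log1p`, depth scaling — leaves scores unchanged,
which also makes depth normalization largely moot) and the extremal
property that a set occupying the top $|S|$ ranks attains the maximum. The
exponent 0.25 is the common single-sample choice and is exposed because the
delegated implementation in the source workflow does not state it.

Group comparisons use the Wilcoxon rank-sum test (exact null for combined
$n \le 20$ without ties, normal approximation with tie correction
otherwise) or Kruskal-Wallis, with optional Benjamini-Hochberg adjustment
across the features of a call. Correlations are Pearson or Spearman via the
t approximation with listwise deletion of non-finite pairs.

# Synthetic data: what it emulates, and what it does not

The generator produces hexagonal lattices (odd rows offset by half a pitch,
rows $\text{pitch}\cdot\sqrt3/2$ apart), niche-structured Dirichlet
compositions, planted point patterns, CNV profiles with gain/loss blocks,
and marker-structured negative-binomial counts
($\mathrm{Var} = \mu + \mu^2/\theta$; $\theta = \infty$ gives Poisson). All
generators are pure functions of (parameters, seed) and restore the
session's RNG state.

Study conditions used by the validation suite and `scripts/acceptance.R`:

* **Niches**: 5 niches on a 30 × 30 lattice (900 spots), 8 cell types,
  Dirichlet precision 30 and dominant-type mean weight 0.6 — moderate
  overlap: the dominant type's weight has spread ≈ 0.09, well separated but
  visibly noisy, our reading of realistic deconvolution output. Candidates
  2–8, 50 gap references, 20 seeds; recovery of $k = 5$ in ≥ 80% of seeds
  and ARI ≥ 0.9 at the true k.
* **Co-localization null**: independent uniform positive sets (60 + 60 of
  400 spots), 99 simulations per test, 200 outer replicates; the rejection
  rate at $\alpha = 0.05$ must fall in the binomial 95% interval around
  0.05. The estimator's unbiasedness is checked separately against
  $\pi r^2$ under *continuous* CSR with $r$ at most 2% of the window side:
  on a lattice, $E[\hat K]$ is quantized by the neighbor shells
  (Gauss-circle steps of ±15% at $r$ of a few pitches), so only the
  continuous null admits the closed-form reference; at these $r$ the
  uncorrected edge deficit (≈ $\tfrac{8}{3\pi} r/S$) is well inside the
  Monte-Carlo band.
* **Co-localization power**: both types' spots drawn around 5 shared
  parents with 50 µm Gaussian spread, 100 spots each on the 900-spot
  lattice; $p \le 0.05$ in ≥ 90% of 50 replicates and median Aggregation
  Index ≥ 0.8.
* **CNV**: 200 reference + 50 malignant cells, 200 bins, one gain block at
  level 1.4 over 25% of bins, noise sd 0.05; sensitivity and specificity
  ≥ 0.95 over 20 seeds.
* **Expression**: marker fold 3 over base mean 5 with dispersion 2 —
  shallow Visium-like counts.

Synthetic data are idealized in known ways: compositions are exactly
Dirichlet with spatially constant concentration, positive sets are exact
subsets of lattice spots (no segmentation error or spot bleed), CNV noise
is i.i.d. Gaussian (inferCNV residuals are smoothed and autocorrelated
along the genome), and counts lack zero inflation and spot-level size
factors. Passing the suite therefore demonstrates correctness of the
estimators and calibration of the tests under their stated assumptions —
not robustness to every artifact of real tissue.

# Numerical choices and degenerate inputs

* Quantiles use R's default linear-interpolation convention (type 7),
  stated because the positive-spot threshold depends on it.
* Row sums of weight matrices within $10^{-6}$ of 1 are renormalized;
  larger deviations are rejected naming the worst row.
* k-means degeneracies (empty clusters, duplicate centers) are retried up
  to 5 times with fresh starts, then raised; $k$ equal to the number of
  distinct rows is fitted exactly (one row per cluster, WSS 0).
* All-equal weights yield an empty positive pattern with a degenerate flag
  and a warning, never an error; empty patterns fail the sample filter with
  a logged reason.
* Cohen's d with $sd(D) = 0$, correlations of zero-variance vectors, and
  similarities of flat CNV profiles are NA/0 with flags, never crashes.
* JSON serialization uses 17 significant digits, so doubles round-trip
  exactly and repeated runs are byte-identical; provenance blocks carry the
  package version, configuration snapshot and seed but no timestamps.
* Envelope ranks use the discard-$\lfloor\alpha(n+1)\rfloor$-per-tail
  convention described above; the floor is evaluated with a $10^{-9}$ guard
  against binary-fraction artifacts (e.g. $0.05 \times 20 < 1$ in floating
  point).

# Problem sizes

The validation suite runs at the sizes quoted above (the largest single
object is the 900-spot lattice with its 900 × 900 distance matrix); the
whole suite completes in about a minute on one core, and
`scripts/acceptance.R` in well under a minute. Larger samples are handled
by the same code paths — the envelope routine precomputes the full
spot-to-spot distance matrix only up to 3000 spots and streams distances
per simulation beyond that.

# Known limitations

* The cross-K suite is homogeneous: no inhomogeneous-K variants, no
  multi-scale view modeling, no ligand-receptor analysis.
* The isotropic correction covers rectangular windows only (sufficient
  here, where windows are padded bounding boxes).
* The co-occurrence binarization is a documented stand-in for the upstream
  tool's unspecified rule; conclusions that depend on the exact presence
  calls should be checked against the `quantileThreshold` setting.
* Joint multi-sample niche clustering is supported by concatenating weight
  matrices (barcodes must be unique across samples); no batch-effect
  modeling is attempted — that belongs upstream.
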
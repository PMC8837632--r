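---
title: "Methods: spatial analysis of lymphoid aggregates in synovial tissue"
author: "spatlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial analysis of lymphoid aggregates in synovial tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`spatlo` analyses barcoded-array spatial transcriptomics (ST) of inflamed
synovium. The measurement unit is a *spot*: a ~100 µm barcoded capture area
with a known array position (x, y) in a section, and a section index that
maps to a depth z (µm) through the cryosection spacing — 7 µm for
consecutive sections, 21 µm when every third section is profiled. A study
volume is a spots × genes count matrix joined to a spot table, optionally
accompanied by a segmented-cell table from the matching H&E image and by
manual annotations (e.g. `"infiltrate"` for visually dense leukocyte
regions).

The biological object of interest is the tertiary lymphoid organ (TLO): an
organized aggregate of infiltrating leukocytes whose core is
lymphocyte-rich and whose surroundings change composition radially —
macrophage-rich tissue closest to the core, sublining fibroblasts further
out, and a CD55⁺ lining-fibroblast layer at the tissue border.

# Preprocessing

**Spot filter.** Spots with fewer than 200 detected genes are removed
(inclusive bound: a spot detecting exactly 200 genes is kept, reading the
threshold as a lower bound on acceptable library complexity). The filter
also guarantees positive totals so later depth models are well defined.

**Normalization.** Two modes are provided:

* `size_factor_log` (simple, non-negative): `log1p(count / sf)` with
  `sf = total / median(total)`. Non-negativity makes this the layer used for
  signature scoring, where scores are sums.
* `regression_residual` (default for clustering): per-gene Pearson
  residuals of a Poisson regression of counts on `log(total)`, clipped at
  ±√n_spots. Unlike a size factor, the regression does not assume counts
  scale proportionally with depth; the clip bounds the influence of single
  outlier spots. Both modes satisfy the contract that matters downstream —
  the per-spot mean normalized value is uncorrelated with depth.

**Variable genes.** Counts are divided by the spot total (the size factor),
then genes are ranked by `CV²_g − median_g(CV²)`. The median subtraction
makes the statistic a *relative* overdispersion measure; its ordering is
identical to CV² ordering, but the statistic is centred so that "typical"
genes sit near zero. CV² is computed on the linear, size-factor-scaled
counts — before any log transform — because the statistic is a ratio of
moments of the counts themselves. Ties are broken by higher mean, then gene
symbol, so selection is deterministic. Typical panel sizes are 100–2000
genes depending on the heterogeneity of the sample.

# Spatial clustering

**Dimension selection.** PCA is computed on the column-centred normalized
matrix restricted to the variable genes. The number of components carried
forward is chosen by a *deflated* permutation test (a parallel-analysis
variant): component k is compared against permutations of the residual
matrix after projecting out the first k−1 accepted components, where each
gene column is shuffled independently across spots and the top eigenvalue
of the shuffled residual forms the null. Deflation matters: without it, the
variance captured by strong leading components inflates the permutation
null spectrum and masks weaker but real structure (we observed rank-3
signal with an eigenvalue *below* the naive rank-3 null on data where the
deflated test correctly recovers it). Testing stops at the first clearly
null component (raw p > 0.25); p-values are BH-adjusted across components
and components significant at 5% FDR are kept, with a floor of two so an
embedding always exists. 200 permutations give p-value resolution of
1/201 ≈ 0.005, enough for the BH step at 20 candidate components.

**Embedding and clustering.** tSNE is run on the selected components with
three output dimensions — hierarchical clustering operates on the first
three tSNE components, so a 3-component embedding is the minimal consistent
choice (a 2-component embedding would leave nothing to cut in the third
dimension). Perplexity defaults to 30 and should be raised (~50) for
volumes above ~1000 spots; it must stay below (n−1)/3. Clustering is
agglomerative with the `ward.D2` criterion on Euclidean distances in tSNE
space, cut at a predefined k (4 for a well-differentiated volume; 2–3 for
infiltrate-only reruns). Labels are renumbered so cluster 1 is the densest
(by mean per-spot cell count when available, otherwise the largest), with
ties broken by the smallest member barcode — making labels invariant to
spot order.

**Differential expression.** Each gene is tested cluster-vs-rest with a
negative-binomial GLM containing a log-depth offset; the gene-wise
dispersion is estimated by matching the Pearson χ² statistic of the
offset-only model to its degrees of freedom (bisection, floored at 1e-8,
i.e. effectively Poisson when the data show no overdispersion). The
likelihood-ratio statistic of the cluster indicator (1 df) gives the
p-value; the effect size is the difference of mean `log1p` size-factor
expression inside vs outside. A gene is a cluster marker when p < 0.001
and log-ratio > 0.5. This estimator was chosen over moment matching on
depth-scaled counts because rescaling inflates the apparent variance and
makes the test conservative; χ² matching keeps the null type-I error at
the nominal rate (validated at 0.03–0.06 on 500-gene null simulations).

**Group contrasts** (e.g. seropositive vs seronegative scores per cell
type) use Welch t tests per feature with BH adjustment at 5%, with the
convention that features constant and equal in both groups get p = 1.

# Cell-type scoring

Signatures are marker tables from reference scRNA-seq: per cell type, the
markers with average log fold-change > 1 (strict) and FDR < 5%, truncated
to the 200 largest fold-changes. Scoring proceeds per type l and spot r:

1. **Presence.** A type is scoreable when more than 3 of its markers
   (i.e. ≥ 4) are present in the matrix; types failing this are reported as
   *not scoreable* rather than zero, so they cannot distort the proportions
   of the others. (The threshold is exposed as `min_markers`; degenerate
   demonstrations with singleton signatures set it to 1.)
2. **Co-expression validity.** Pairwise Pearson correlations are computed
   across spots on the same normalized layer used for scoring. Marker j is
   retained when its *mean* correlation with the type's other present
   markers is positive. A pairwise rule ("correlation > 0") has to be
   reduced to a per-gene decision somehow; the mean rule is the closest
   per-gene reading and coincides with the pairwise rule for two markers. A
   stricter `all_pairs` mode (every correlation positive) is provided for
   comparison. Zero-variance markers have undefined correlations and are
   dropped with a warning.
3. **Raw score.** `c_{l,r} = Σ_{m ∈ M_l} Y_{m,r}`, the sum of the retained
   markers' normalized expression (non-negative on the `size_factor_log`
   layer).
4. **Max scaling.** `C_{l,r} = c_{l,r} / max_r c_{l,r}` puts all types on a
   common [0, 1] scale; each type's best spot scores exactly 1.
5. **Proportions.** Within each spot, max-scaled scores are divided by
   their sum over scoreable types, yielding vectors that sum to 1 and
   approximate the relative cell-type composition. The per-spot reading of
   the cumulative score is the one consistent with interpreting the output
   as a composition; a per-type-over-spots alternative
   (`proportion_mode = "per_type"`) is provided for comparison only, since
   normalizing each type over spots cannot produce compositions.

Scale invariance is built in: doubling every normalized value leaves
max-scaled scores and proportions unchanged. Scoring is equivariant under
cell-type permutation and invariant under spot permutation.

**Co-localization** of two score maps is their Pearson correlation across
spots with a two-sided p-value; undefined (NaN, with warning) when a map is
constant.

# TLO detection and the cell table

Segmented cells are assigned to the spot whose axis-aligned square window
(side = 200 px for the original 100 µm spot frame; generally one spot
pitch) contains their centroid, boundaries inclusive. Spots without any
cell are flagged for removal — a spot with no detected nuclei has no
morphology to couple to. The *density score* of a spot is the percentile
rank (0–100, average ranks for ties, a lone spot scoring 50) of its cell
count *within its section*, making the score invariant under any strictly
monotone transform of the counts and robust to section-to-section staining
differences. Spots strictly above the 70th percentile are TLO candidates;
with well-separated aggregates this flags the densest ~30% of spots, and
the fraction of manually annotated infiltrate spots captured by the rule
(`annotation_overlap`) is the headline diagnostic.

The density score is deliberately minimal — a percentile of window cell
counts, with no kernel smoothing — because it is the simplest statistic
that supports the downstream claims; any monotone density estimator would
give the same ranking.

# 3D reconstruction

**Registration.** Sections are aligned to a reference section by
least-squares point-set registration on spot coordinates: the similarity
transform (rotation θ, isotropic scale s, translation) minimizing the RMSD
between corresponding points, computed in closed form (Umeyama's solution);
`rigid` mode fixes s = 1. When sections share barcodes, correspondences are
exact and recovery of a synthetic transform is accurate to machine
precision; otherwise correspondences come from nearest-neighbour matching
after centroid/principal-axis pre-alignment, refined by ICP iterations.
Registering points rather than images keeps the transform family
(rigid/scaled-rotation) while making the operation testable against known
ground truth.

**Interpolation.** Per-section scalar fields (expression, scores) are
interpolated on the Delaunay triangulation of the registered spot
positions, evaluated on a regular grid, with nodes outside the spots'
convex hull masked. Piecewise-linear interpolation was chosen over a cubic
spline because it reproduces linear fields exactly and never overshoots —
testable contracts that matter more than smoothness for a visualization
layer. No interpolation is performed along z: stacking the per-section
grids in z order *is* the volume, and slices equal the 2D results exactly.

# Receptor–ligand interactions and enrichment

For each receptor–ligand pair and spot subset (e.g. the TLO cluster of one
patient group), the statistic is the mean of the two partners' average
normalized expression in the subset. The null is built by permuting subset
labels across spots (one shuffled label vector per iteration, evaluated for
all pairs, as in cell-level permutation frameworks); the p-value uses the
add-one convention `(1 + #{null ≥ obs}) / (n_perm + 1)`, so p is never 0
and is super-uniform under exchangeability. The effect size is the natural
log of the subset statistic over the all-spot statistic; pairs with
log-ratio > 0.1 and p < 0.01 are reported. Because permutations are shared
across pairs within a run, empirical false-positive rates should be
estimated across independent datasets (the tests average five).

Gene-set over-representation is the hypergeometric upper tail
`P[X ≥ k]` against a user-supplied universe, BH-adjusted across sets,
reported at 5% FDR. Zero overlap gives p = 1 by construction; a query that
saturates a set (overlap at its forced minimum, positive) is flagged as
degenerate.

# Power analysis

The study design question is nested: patients within groups, sections
within patients, annotated spots within sections. The simulated outcome is
`y = β·group + u_patient + v_section + ε` with independent normal random
effects and `β = effect_size·√var_resid` (effect sizes in residual-SD
units, so designs are comparable across noise levels). The group effect is
tested by a Welch t test on patient means: with balanced nesting, patient
means are sufficient for the group contrast, the test is valid (exactly
accounts for between-patient variance) and conservative, and it avoids
fitting a mixed model inside the Monte-Carlo loop; an `lmm_wald` mode
(lme4 random-intercept fit, Wald z) is available for comparison. Power is
the rejection fraction at α with Monte-Carlo SE `√(p(1−p)/n_sim)`.

Defaults (patient variance 0.5, section variance 0.25, residual 1) describe
a noisy clinical setting; they are placeholders to be replaced with
pilot-data estimates, since variance components for this tissue are not
established. `design_search` evaluates a design grid under common random
numbers (one shared seed), which keeps estimated power monotone along each
grid axis in practice, and returns the undominated frontier of designs
meeting the target (default 80% power). At small patient counts
(n ≤ 4 per group) the Welch test is mildly conservative — size ≈ 0.035 at
nominal 0.05 — which is the safe direction for design decisions; size is
within Monte-Carlo error of nominal from ~6 patients per group.

# The synthetic-data generator

`simulate_volume` emulates the structures the pipeline is meant to detect,
with full ground truth:

* spots on a jittered grid per section (default 3 sections × 650 spots,
  matching a 1000–2000-feature array partly covered by tissue);
* one central aggregate (radius 20 array units on a 100-unit array) with
  radial zones: TLO core, two rings (1.6× and 2.3× the core radius), and
  lining tissue;
* six reference cell types — B cells, T cells, THY1⁺ sublining fibroblasts,
  macrophages, dendritic cells, CD55⁺ lining fibroblasts — with disjoint
  25-gene marker blocks at natural-log fold-change 2 over a shared
  lognormal background. Distinguishing the two fibroblast compartments is
  what gives the lining zone its own expression identity;
* zone-specific mixture profiles (lymphocyte-rich cores in the seropositive
  configuration, fibroblast/DC-rich cores in the seronegative one; a
  macrophage-rich inner ring; a DC gradient peaking in the outer ring and
  depleted in the lining), drawn per spot from a Dirichlet with
  concentration 150 — enough spot-to-spot variability for
  proportion-recovery checks while keeping zones coherent;
* expected expression `depth × (proportions · signature_matrix)` with
  lognormal depth (mean 3000 counts, sdlog 0.3) and negative-binomial
  counts (size 5, a typical ST overdispersion; `Inf` recovers Poisson);
* a cell table with Poisson cell counts per spot window (expected 45 in
  cores down to 10 in lining) and small cell areas in cores (lymphocytes)
  versus large outside (fibroblasts, macrophages), plus `"infiltrate"`
  annotations on core spots.

All randomness flows from a single seed through a private RNG stream, so
runs are byte-reproducible and never disturb the caller's RNG. The
generator's count model omits several features of real ST data — zero
inflation beyond NB, gene–gene correlation beyond the mixture structure,
segmentation errors, section-to-section batch effects, and imperfect
manual annotation. Passing tests on simulated volumes therefore validate
the *implementation* of each stage and the pipeline's behaviour under its
own assumptions; they do not certify performance on real tissue, where
normalization residue and annotation noise will lower recovery rates.

# Validation problem sizes

The test-suite and acceptance-script runs use these scales, chosen to
estimate each quantity with useful precision while keeping a full run in
minutes: proportion recovery on five volumes of 2001 spots × 1000 genes ×
5 cell types; cluster recovery on five volumes of 1000 spots × 400 genes
(4 zones, k = 4, perplexity 50); PC-rank recovery on twenty 120 × 60
matrices with planted rank 2 (199 permutations); DE calibration on a
200 × 500 null; interaction calibration on five 150 × 400 nulls with 200
pairs and 1000 permutations each; power calibration at 2000 Monte-Carlo
replicates. The full-size clustering example (1950 spots, 500 variable
genes, 20 candidate PCs × 200 permutations) runs in a few minutes,
dominated by the deflated permutation test.

# Known limitations

* The co-expression validity rule and the per-spot proportion
  normalization are interpretations of an under-specified scheme; both
  alternatives are implemented and switchable, and conclusions should be
  checked against them.
* Signature-sum scoring is not a deconvolution: proportions are relative
  signature intensities, not calibrated cell fractions, and types with
  correlated signatures will bleed into each other.
* ICP registration without shared barcodes needs a reasonable
  pre-alignment; tissues with near-rotational symmetry can lock into a
  wrong axis.
* The NB dispersion is estimated per gene under the null model; very small
  clusters (< 3 spots) are rejected rather than tested.
* tSNE + ward.D2 clustering has irreducible stochastic variability between
  seeds; cluster-recovery ARIs of 0.85–0.98 across seeds are expected on
  simulated volumes of ~1000 spots.
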
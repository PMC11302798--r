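---
title: "Evaluating tumor segmentations with radiomics ICC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating tumor segmentations with radiomics ICC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radagree)
```

## The problem

When several readers or several pieces of software segment the same tumor,
the standard way to quantify their agreement is geometric: the Dice
similarity coefficient (DSC), the surface Dice coefficient at a distance
tolerance (sDSC), and the Hausdorff distance (HD). These metrics saturate
quickly. Two segmentations that overlap by 90% of their volume score a DSC
near 0.9 whether their disagreement is a random ripple of the boundary or a
systematic one-voxel expansion applied by one tool everywhere — yet those
two error modes have very different consequences for any quantity computed
from the segmented region.

`radagree` implements a complementary, feature-based evaluation: extract a
standardized radiomics panel (intensity statistics, shape, and five
texture-matrix families over a bank of filtered images) from every
segmentation of every tumor, and quantify between-segmentation agreement
per feature with the intraclass correlation coefficient from a two-way
ANOVA. Because the ICC in its absolute-agreement form penalizes systematic
rater offsets, features that respond to consistent differences between
segmentation methods expose those differences far more sensitively than
any overlap score.

## The feature panel

Each (image, mask) pair is processed as follows.

1. **Resampling.** Image and mask are resampled to an isotropic grid
   (default 2 mm voxels) covering the native physical extent,
   center-aligned. The image is interpolated trilinearly, the mask with
   nearest-neighbor and re-binarized. All later physical quantities (mm,
   mm^2, mm^3) refer to this grid. Trilinear interpolation is the single
   image interpolation rule of the package: at the smoothness of CT-like
   data the difference from higher-order schemes is far below the
   between-segmentation effects under study, and one documented rule keeps
   the geometry auditable.
2. **Filter bank.** Ten derived images per case: the resampled original, a
   Laplacian-of-Gaussian response at sigma = 1 mm (sum over axes of
   separable second-derivative-of-Gaussian kernels, sampled per-axis in
   physical units, zero-sum corrected), and the 8 sub-bands of a
   single-level stationary (undecimated) separable 3-D wavelet
   decomposition. The wavelet family defaults to `coif1`; the i-th letter
   of a sub-band label names the filter (L/H) applied along grid axis i.
   All filters share one boundary rule: symmetric (edge-repeating mirror)
   padding. The transform is undecimated precisely so every sub-band stays
   on the ROI grid.
3. **Discretization.** ROI intensities of each derived image are mapped to
   integer gray levels with a fixed bin width (default 25 intensity units),
   `level = floor((x - min(ROI)) / width) + 1`. Anchoring the first bin at
   the ROI minimum guarantees level 1 is occupied; a config flag switches
   to bin edges aligned at multiples of the width for studies that prefer
   an absolute scale. The bin origin is recorded alongside the output.
4. **Features.** Per derived image, 93 features: 18 first-order statistics
   (order statistics on raw filtered intensities; entropy/uniformity on the
   discretized histogram), 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and
   5 NGTDM texture features. GLCM and GLRLM are built per direction over
   the 13 unique 3-D neighbor directions at distance 1 and averaged without
   distance weighting; GLSZM zones and GLDM dependencies use
   26-connectivity. On top of these 930 come 14 shape descriptors of the
   resampled mask, for a panel of 944 features per segmentation. Feature
   names and formulas follow the public IBSI-style definitions used by the
   standard extractors, so tables are comparable across tools.

### The surface mesh

Shape area and volume come from a triangulated surface. The mask is
smoothed with a Gaussian of one voxel per axis, the result clamped so every
foreground voxel stays above the 0.5 iso-level and every background voxel
below it, and the iso-surface is triangulated by marching tetrahedra on the
Freudenthal cube split with linear interpolation along cell edges. The
Freudenthal split is face-consistent across cells, so the mesh is closed
and its divergence-theorem volume is exact for the mesh. The mollification
matters: meshing the raw binary indicator overestimates the area of curved
surfaces by roughly a quarter (the staircase effect), which would push the
sphericity of a large rasterized ball to ~0.79 instead of ~0.99. The cost
is at the opposite extreme: structures thinner than about one voxel retain
only a tiny clamped mesh, and sharp edges are slightly rounded (a 10-voxel
cube reads ~15% low in area, ~9% low in volume). Tumor-scale blobs — the
object of this package — sit comfortably on the favorable side of that
trade. Maximum 3-D/2-D diameters are defined between boundary voxel
centers (6-connectivity boundary), and the principal axis lengths are
`4*sqrt(eigenvalue)` of the voxel-center covariance with a 1e-12
eigenvalue floor for degenerate masks.

## Geometric metrics

DSC is computed on foreground voxel sets; sDSC and HD on boundary surfaces,
where the boundary is the set of foreground voxels with a 6-connected
background (or out-of-grid) neighbor and distances are Euclidean distances
between voxel centers in mm, evaluated with an exact anisotropic distance
transform. HD is the plain symmetric maximum (not a percentile variant).
The sDSC tolerance defaults to 2 mm — one voxel at the default resampled
spacing — and is always recorded next to the value, since sDSC is only
interpretable jointly with its tolerance. Metrics are computed on the
resampled grid, consistent with feature extraction.

## The ICC engine

For a complete n tumors x k segmentations matrix of one feature, the
two-way ANOVA mean squares (between-subject MSR, between-rater MSC,
residual MSE) give the single-measure absolute-agreement ICC:

$$\mathrm{ICC}(A,1) = \frac{MSR - MSE}{MSR + (k-1)\,MSE + \tfrac{k}{n}(MSC - MSE)}$$

The point estimate is identical under random- and mixed-rater assumptions
(the "two-way mixed model for absolute agreement" reading); only the
interpretation differs. 95% bounds use the F-based interval with
Satterthwaite degrees of freedom evaluated at the point estimate. Negative
estimates are reported as computed, never truncated: a strongly negative
pairwise ICC is informative (rater disagreement exceeding subject
variance). A matrix with no variance at all is returned as a flagged
degenerate result rather than a number. The implementation is locked
against an independently written ANOVA-based oracle and against an external
reference implementation on frozen matrices.

Two ICC views are used downstream: **ICC\*** — one value per feature from
the full n x k matrix — and the **36 pairwise ICCs** per feature from the
n x 2 matrices of every unordered segmentation pair (k = 9).

## The analysis pipeline

* `screen_features()` computes ICC\* for the whole panel, discards
  degenerate features, and keeps the features inside a low-reproducibility
  band (default [0.1, 0.51]). The default selection takes the `n_select`
  (10) lowest-ICC\* features in the band — a reproducible, monotone rule —
  with an explicit-list override for forcing a published feature set.
  No multiple-testing adjustment is applied anywhere: the screen ranks and
  counts features, it does not test hypotheses.
* `build_agreement_map()` fills a k x k symmetric matrix of pairwise ICCs
  per selected feature (diagonal 1 by convention) plus their element-wise
  mean. The mean map across the selected features drives clustering —
  per-feature maps are kept for heat-map inspection, but a single partition
  needs a single aggregated similarity.
* `discover_classes()` runs average-linkage hierarchical clustering on
  `1 - mean ICC` (ICC floored at -1, distances in [0, 2]) and cuts at
  `n_classes` (default 3; `"auto"` maximizes mean silhouette over 2..k-1,
  scoring singleton clusters 0). Deterministic given the map.
* `rate_against_reference()` reproduces the gold-standard reading: pick a
  reference segmentation, tabulate each other segmentation's pairwise ICC
  against it across the selected features, and call a segmentation
  discordant when all (or, configurably, the median of) its ICCs fall
  below a threshold (default 0.5).
* `metric_comparison_report()` joins tumor-averaged DSC/sDSC/HD per pair
  (36 rows) with the per-feature pairwise ICCs — the scatter data showing
  ICC spreading widely while DSC and sDSC sit in a narrow band. Points are
  emitted per feature and pooled, since either reading of a joint plot is
  legitimate.

## The phantom generator

Real multi-institution segmentation data cannot ship with a package, so
`radagree` generates a synthetic cohort that reproduces the *design* of
such studies: `n` tumors, each segmented `k = families x settings` times,
where a family is one systematic error pattern (one "institution's
software") and its settings vary only the strength.

Each tumor is an ellipsoid (semi-axes uniform in 20-26 mm) on a 64^3 grid
at 1 mm spacing, with correlated internal texture (Gaussian-filtered white
noise, 3 mm correlation length, amplitude 30), a tumor-background contrast
of 100, additive white noise (amplitude 10), and tumor-to-tumor
heterogeneity: each tumor scales contrast and texture amplitude by a
factor uniform in 1 +/- 0.4. That heterogeneity emulates the strong
between-patient variability of real tumors; it is what makes most features
highly reproducible across segmentations (high ICC\*) so that the low-ICC\*
tail isolates the segmentation-sensitive ones.

The three default families:

* **boundary_jitter** (random): a smooth random displacement field, *one
  field per tumor and family*, applied at amplitude sigma = 1.0/1.1/1.2 mm
  — the three settings share the same error pattern at graded strength,
  like one tool run at different aggressiveness.
* **systematic_dilation**: morphological dilation by 1.45/1.6/1.75 mm.
* **systematic_erosion_offset**: erosion by 1.0/1.15/1.3 mm plus a rigid
  shift of (0.8, 0.6, 0) mm times the level, rounded to whole voxels.

Two discreteness facts shaped these defaults and are worth knowing before
changing them. First, on a 1 mm grid a morphological level below 1 mm does
nothing: the smallest dilation/erosion step is one voxel. Second, the
low-ICC\* features selected by the screen are precisely the ones
hypersensitive to the exact composition of the added or removed boundary
shell, so two settings of one family must *not* straddle a discrete
morphology threshold (voxel distances 1, sqrt(2), sqrt(3), 2): a family
whose settings differ by a whole extra shell decorrelates internally as
strongly as two different families. The default levels keep each family's
settings inside one discrete window — their masks differ sub-voxel or not
at all — which is exactly the "same method, slightly different parameters"
situation the cohort is meant to emulate.

All levels are of the order of one voxel, so every within-tumor pairwise
DSC stays above 0.75 (checked at generation; a violating tumor regenerates
with levels scaled down by 20%, bounded retries). Everything derives
deterministically from one seed via hierarchical sub-seeding.

What the phantom does **not** emulate: lung anatomy and CT physics
(attenuation, partial volume, reconstruction kernels), human contouring
behavior, inter-observer semantics (what *should* be included in a GTV),
and tumor shapes beyond smooth ellipsoids. A passing synthetic run
therefore demonstrates that the pipeline's statistics behave as designed
under a controlled error model — not that any particular clinical dataset
will separate into clean method families.

## Numerical conventions

* Degenerate gray-level situations follow fixed conventions: a
  single-level ROI has MCC = 1, ClusterShade/Prominence = 0,
  Correlation = 1; an isolated-voxel NGTDM returns Coarseness = 1e6 (the
  customary cap) and 0 elsewhere.
* Machine epsilon (2.22e-16) guards every logarithm and division in the
  texture formulas; entropies use log base 2.
* GLCM/GLRLM directions that produce no pairs (e.g. along a singleton
  axis) are skipped, and features average over the remaining directions.
* Distances compare voxel centers; surface elements are boundary voxels.
  The sDSC tolerance check uses `d <= tol + 1e-9` so exact-tolerance
  distances count as within.
* ICC confidence bounds fall back to the residual degrees of freedom when
  the Satterthwaite expression degenerates (e.g. at ICC = 1, where the
  interval collapses to a point).
* Clustering distances clamp ICC at -1; missing (degenerate) cells enter
  the mean map as 0 — a neutral "no evidence of agreement" value.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
oracle equivalence on 200 random volumes up to 6^3 voxels, ICC oracle
agreement on 500 random 10 x 9 matrices, and the headline contrast on the
default 10-tumor cohort at 64^3 with class-discovery recovery scored over
100 independently seeded cohorts (extracting only the selected features on
the replicate cohorts — selection transfers by feature identity, and the
restricted extraction is what makes 100 replicates affordable). These
sizes are the package's chosen desk-scale study conditions; the pipeline
itself has no scale assumptions beyond memory.

## Known limitations

* Only axis-aligned geometries are supported; oblique acquisitions must be
  resampled upstream.
* The mesh area/volume of sub-voxel-thin structures is degenerate (tiny),
  as discussed above.
* The ICC engine requires complete rating matrices; missing segmentations
  must be handled (dropped or imputed) before analysis.
* Fixed-bin-count discretization, per-slice (2-D) features, and gray-level
  normalization beyond the shift-invariant bin origin are out of scope.
* With n = 10 subjects a pairwise ICC carries wide sampling error; the
  pipeline leans on the mean over selected features and on 36 pairs, not
  on any single pairwise value.
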
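---
title: "Quantifying spatial neuropathology with neuroprox: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial neuropathology with neuroprox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In amyloid mouse models of Alzheimer's disease, the questions that matter
are spatial: are activated microglia sitting closer to soluble amyloid-beta
oligomers than to compact plaques? Does synaptic marker density fall off
with distance from a deposit? Which combinations of glial markers travel
together at the single-cell level? Multiplexed tissue imaging — imaging
mass cytometry (IMC) at roughly 1 micrometre per pixel, or chromogenic
(DAB-style) immunohistochemistry — produces the raw material, but turning
co-registered intensity rasters into those answers requires a chain of
steps: per-pixel classification, nucleus-seeded cell segmentation,
morphometry, ring-based proximity statistics, per-cell marker correlation
and graph-based phenotyping. `neuroprox` implements that chain as tested,
reusable R functions, together with a synthetic-scene generator that
provides exhaustive ground truth so every stage can be validated against a
known answer.

```{r, eval = FALSE}
library(neuroprox)
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "demo_run")
```

## The synthetic scene generator

Because real multiplexed images of this kind are rarely deposited, the
package treats simulation as a first-class module rather than a test
fixture. A `scene_config()` describes a field at micrometre resolution
(default 1 um/px, the IMC ablation raster) containing:

* **Plaques** — compact deposits rendered as discs whose boundary radius is
  modulated by a smooth two-harmonic angular perturbation of up to 20%.
  Real plaques are variably dense and irregular; the perturbation avoids
  trivially circular geometry while keeping the analytic disc-area
  approximations useful for oracles. Plaques are placed with a 1-px
  hard gap so the label image always contains exactly `n_plaques` objects.
* **An oligomer halo** — noiseless intensity
  `I0 * exp(-d / tau)` at distance `d` from the nearest plaque edge
  (default `tau` = 30 um, truncated at `6 * tau`). This encodes the
  observation that oligomer staining concentrates in and immediately
  around plaques, and gives the Sholl stage a decaying target whose ring
  profile is known in closed form.
* **A diffuse oligomer component** — small blobs covering a configurable
  fraction of the plaque-free area. The morphology of diffuse,
  process-like oligomer staining is not quantitatively characterised in
  the literature; this component is an explicit stand-in and is labelled
  as such wherever it is used.
* **Nuclei** — a hard-core point process (discs, default radius 3 um,
  centre separation at least one diameter plus 1 px). Because somata are
  rendered on their own marker channels, the nucleus channel contains
  exactly `n_nuclei` non-touching objects — which is what makes the
  segmentation count-recovery tests well defined.
* **Cells** — per marker, `n_cells` somata plus random-walk processes.
  Centroids are drawn from the density
  `lambda(d) = w * exp(-d / tau_attr) + (1 - w)`, the simplest mixture
  that spans complete spatial randomness (`w = 0`) and strong pathology
  attraction (`w = 1`). Somata never overlap (bounded rejection sampling,
  10^4 retries, then an `infeasible_scene` error — counts are realised
  exactly or loudly, never silently reduced).
* **Noise** — per pixel `Poisson(s * I) / s + N(mu_bg, sigma)` clipped at
  zero, the usual shot-plus-read model. "SNR about 5" in the validation
  scenes means peak signal 100 against a combined noise sd of about 20
  (Poisson sd 10 at `s = 1` plus Gaussian sd 17).

All randomness flows from the single `seed`; identical configurations
reproduce byte-identical stacks.

What the generator deliberately does **not** emulate: 3-D structure,
spectral spillover, uneven illumination, tissue folds, autofluorescence,
and realistic glial morphology (processes are random walks, not ramified
arbours). Passing tests therefore demonstrate that the *algorithms* are
correct and well calibrated on images with the assumed spatial structure —
not that any particular biological effect size would be recovered from
real tissue.

## Pixel classification

Features per channel: the raw intensity plane plus, per scale sigma
(default 10 px, matching the feature-scale convention of interactive pixel
classifiers at this resolution): Gaussian-smoothed intensity, gradient
magnitude of the smoothed image, and texture operationalised as the two
structure-tensor eigenvalues plus the Laplacian of Gaussian. The raw plane
matters: smoothed features cannot localise a crisp object boundary to the
pixel, and without it classification accuracy on noiseless scenes saturates
below the pixel-exact level.

The classifier is a bagged probability-tree ensemble (100 trees, depth at
most 12) — the same family that interactive tools train. Two
non-defaults are deliberate:

* `mtry` defaults to half the feature count rather than the square root,
  so the decisive raw-intensity planes are available at most splits;
* annotations are canonically sorted (class, then y, then x) before
  training, making the fitted model invariant to annotation row order at a
  fixed seed — an invariance the bootstrap would otherwise break.

The class set defaults to `signal` / `nuclei` / `background`. A class
required but absent from the annotation is an error; two-class problems
must be declared explicitly via `classes`. Interactive workflows usually
train one classifier per composite image rather than per channel; that is
the default here too (features from all channels are concatenated).

## Segmentation

The three-tier scheme: `identify_primary()` thresholds the nuclei
probability map (default 0.5), fills holes, declumps by
distance-transform watershed, and filters nuclei to 10–500 um^2.
`identify_secondary()` grows exactly one cell per nucleus, stopping at a
10 um expansion cap and where signal probability falls below threshold;
contested pixels go to the nearer nucleus by exact Euclidean distance with
ties to the lower label (a deterministic Voronoi rule), or through the
probability landscape when the watershed method is selected.
`identify_tertiary()` is the exact set difference, so
`area(tertiary) = area(secondary) - area(primary)` holds per object by
construction.

Conventions that affect counts and must be known to compare outputs:
foreground connectivity is 4-connected; labels are dense `1..N` ordered by
each object's first column-major pixel; coordinates in exported tables are
0-based `(row, column)` with areas in um^2 = pixel count times the squared
pixel size.

A numerical subtlety: the underlying Euclidean distance transform is
computed in single precision, which makes "distance exactly equal to the
radius" comparisons position-dependent at the 1e-6 level. All distances
are therefore snapped to 1e-3 px before thresholding, so expansion caps
and ring boundaries behave identically for congruent objects anywhere in
the image.

## Quantification

* `area_fraction()` — percent of region pixels at or above threshold;
  thresholds may be fixed numbers, Otsu, or "strictly positive".
* `optical_density()` — Beer–Lambert `-log10(I / I0)` averaged over the
  region. `I0` defaults to the 99th-percentile intensity, a robust
  per-image background estimate; intensities are clipped to
  `[I0 * 1e-3, I0]` so per-pixel OD lies in [0, 3], with the clip count
  reported. The clipping is the price of using a percentile reference on
  images that legitimately contain brighter-than-reference pixels.
* `cell_density()` — count / area, in cells per mm^2.
* `perisomatic_morphometry()` — process area and skeletonised process
  length within a 10 um annulus around each soma (the annulus is
  nearest-soma partitioned, same tie rule as segmentation). Length is
  defined as: Zhang–Suen skeleton, chain-code length (orthogonal link 1,
  diagonal sqrt(2)), plus an endpoint correction equal to the local
  inscribed radius (distance-transform value) at each skeleton endpoint.
  Thinning erodes the ends of elongated shapes by about their half-width;
  the correction reconstructs exactly that, and makes a 3-px-wide bar
  extending 8 um measure 8 um. For compact blobs the skeleton degenerates
  towards a point and the estimate is only accurate to about the blob
  diameter — lengths are process measures, not blob measures. Positive
  fragments outside every annulus are excluded and counted separately.

## Ring-expansion (Sholl) proximity analysis

`build_rings()` grows `n_rings` (default 3) rings of thickness `t`
(default 30 um) outward from the ROI set: ring `k` is the set of pixels at
distance `((k-1) t, k t]` from the nearest ROI pixel, computed with a
single exact distance transform. This gives union semantics directly — a
pixel reachable from several ROIs lands in the smallest applicable ring —
which is the behaviour of enlarging an ROI set by equal distances, and is
documented because averaging per-ROI profiles would differ. The ROI
interior is excluded by default; setting
`exclude_roi_interior = FALSE` reports interior coverage as a "ring 0" row
rather than distorting the ring raster.

Rings clipped by the image border are retained and flagged: the full ring
area is computed on a canvas padded by the total ring reach, and the
retained fraction is attached per ring. A ring clipped away entirely is
reported as missing (NA coverage), never as zero.

`ring_coverage()` is then simply percent positive area per ring, and
`compare_profiles()` layers the statistics the figures need: a one-way
ANOVA of coverage across rings within marker (with eta squared), per-ring
between-marker contrasts (paired when image sets match) with Cohen's d,
and a marker-by-ring two-way ANOVA when the design is balanced.

## Per-cell correlation and phenotyping

`cell_marker_correlation()` computes per-cell mean intensities over cell
masks dilated by 4 px (the conventional pixel expansion, applied to the
mask before intensity extraction; contested pixels again to the nearer
cell) and Pearson r across cells per marker pair. Zero-variance markers
are reported as missing with the reason, not silently dropped, and not an
error.

`cluster_cells()` is Phenograph-style: a k-nearest-neighbour graph
(Euclidean on arcsinh-transformed intensities, default cofactor 5 and
`k = 15`, cytometry conventions), Jaccard shared-neighbour edge weights,
Louvain modularity maximisation — plus a consolidation pass. Plain
modularity maximisation has a well-known tendency to fragment a large
homogeneous population on a sparse neighbourhood graph into several
communities of similar profile. The consolidation merges two communities
while the edge weight crossing between them exceeds a threshold (default
0.04) times the total incident weight of the smaller one. The threshold
sits in a wide gap: fragments of one population share a dense boundary
(relative cross-linkage around 0.1–0.5), while genuinely separated
populations are near 0. The default was calibrated on simulated Gaussian
mixtures so that well-separated populations (5 sigma offsets) stay apart
while a single homogeneous population consolidates to one cluster; both
properties are exercised in the test suite over many seeds. Clustering is
row-order invariant (cells are processed in a canonical profile order) and
deterministic given the seed.

`assign_phenotypes()` names clusters from sign rules
(`c("IBA1+", "APOE+", "TREM2+")` and the like): a marker is "positive" in
a cluster when the cluster's mean transformed intensity exceeds the
across-cluster median plus 0.5 raw MAD (MAD without the normal-consistency
constant). The most specific fully-matching rule wins; exact ties report
all tied names; no match yields `"unassigned"`. Note the threshold is
relative across clusters: a marker uniformly high in *most* clusters will
not be called positive in any — rules should use markers that
discriminate. t-SNE or other embeddings are display-only concerns and
play no part in cluster assignment.

## The statistics layer

`shapiro_wilk()`, `one_way_anova()`, `two_way_anova()`, `tukey_hsd()` and
`pearson_cor()` wrap the standard R implementations behind exact
small-sample contracts: a zero-variance sample is a reported degenerate
result (not a crash); an all-identical response gives F = 0, p = 1; a
perfect fit (zero residual) gives F = 0 or infinity by whether the effect
sum of squares is zero, instead of an unstable 0/0; two-way ANOVA accepts
only balanced full-factorial designs with replication and names the
offending cells otherwise — in a balanced design all sums-of-squares types
coincide, so no silent type choice is ever made. Figure legends in this
literature sometimes carry fractional degrees of freedom, implying
sphericity-corrected repeated-measures ANOVA; no such correction is
implemented here, deliberately — the methods of record state only one- and
two-way ANOVA, and repeated-measures modelling is out of scope.

## Input and output

Stacks are multi-page TIFFs with a sidecar CSV carrying channel names,
per-channel intensity scales and the pixel size (32-bit TIFF pages are
stored on a [0,1] scale, so intensities round-trip to about six
significant digits; label images are 16-bit and round-trip bit-exactly).
Pixel-size precedence is argument over sidecar over a 1 um default. All
tables are CSV at 17 significant digits with units in the column names, so
numeric round trips are lossless and reruns are hash-comparable.
`run_pipeline()` writes a run directory (`images/`, `labels/`, `tables/`,
`manifest.yaml`) where the manifest records the package version, seeds,
per-stage parameters, stage timings and the MD5 of every artefact. The
exported functions are the interface; there is no separate shell
executable — scripted use goes through `Rscript` and these functions, as
the acceptance script demonstrates.

## Problem sizes and validation settings

The test suite and `scripts/acceptance.R` exercise the pipeline at sizes
chosen to make hundreds of full scene-to-statistics runs routine on a
laptop-class single core: validation scenes are 160–300 px square with
3–5 plaques and tens of cells; the ring-geometry oracle uses a 30 um
circular ROI on a 260-px field; spatial null and proximity properties use
100 seeds; count recovery and clustering recovery use 20 seeds; the
statistical null calibrations use 1000–2000 replicates; the end-to-end
demo is a 256-px scene with three markers, run twice and hash-compared.
Scaling any of these up is a matter of configuration, not code.

## Known limitations

* 2-D only; no colour deconvolution of mixed stains; no batch-effect
  handling across images; no learned instance segmentation.
* Skeleton length is a 1-px chain estimate: accurate for elongated
  processes, approximate (to the diameter) for compact blobs, and
  orientation-dependent at the level of single pixels.
* The oligomer "diffuse component" is a stand-in for morphology the
  source literature does not quantify.
* The phenotype positivity rule is relative across clusters and needs at
  least a handful of clusters to be meaningful.
* Cluster count from modularity-based community detection is
  resolution-dependent; the package validates partition recovery (ARI)
  and the homogeneous-population null, not any particular cluster count.
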
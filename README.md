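# neuroprox

Spatial quantification of amyloid pathology and glial/neuronal proximity
in multiplexed tissue images.

## What it is for

Studies of amyloid mouse models ask spatial questions of micrometre-scale
multi-channel images (imaging mass cytometry at ~1 µm/px, chromogenic
immunohistochemistry): how much area do Aβ plaques and oligomers occupy,
how are glial and neuronal markers distributed in concentric rings around
those deposits, which markers co-vary cell by cell, and which marker
combinations define cell phenotypes. `neuroprox` implements the full
analysis chain as R functions:

* **Synthetic scenes with ground truth** — plaque-like deposits, an
  exponential oligomer halo `I₀·exp(−d/τ)` around them, scattered nuclei,
  and soma-plus-process cells whose placement density
  `λ(d) ∝ w·exp(−d/τ_attr) + (1−w)` mixes complete spatial randomness
  with pathology attraction, plus Poisson + Gaussian noise
  (`simulate_scene()`).
* **Pixel classification** — intensity / edge / texture features at a
  configurable Gaussian scale (default σ = 10 px) and a bagged
  probability-tree classifier producing signal / nuclei / background
  probability maps (`extract_features()`, `train_pixel_classifier()`,
  `predict_probabilities()`).
* **Three-tier segmentation** — nuclei (primary), cells grown from nuclei
  (secondary), cytoplasm as the exact set difference (tertiary), with
  deterministic Voronoi tie-breaking (`identify_primary()` /
  `identify_secondary()` / `identify_tertiary()`).
* **Quantification** — marker area fraction (%), Beer–Lambert optical
  density −log₁₀(I/I₀), cell density (count/mm²), and perisomatic process
  length and area within 10 µm of each soma (`area_fraction()`,
  `optical_density()`, `cell_density()`, `perisomatic_morphometry()`).
* **Object-centric Sholl analysis** — 3 rings × 30 µm grown outward from
  deposit boundaries, target-marker area coverage % per ring, with
  clipped-ring flags and profile comparison statistics (`build_rings()`,
  `ring_coverage()`, `compare_profiles()`).
* **Per-cell correlation with 4-px mask expansion and Phenograph-style
  phenotyping** — kNN graph, Jaccard weights, modularity communities with
  a cross-linkage consolidation pass, heat-map summaries and rule-based
  phenotype names (`cell_marker_correlation()`, `cluster_cells()`,
  `assign_phenotypes()`).
* **Statistics** — Shapiro–Wilk, one-/two-way ANOVA (balanced), Tukey HSD
  and Pearson correlation with exact degenerate-case contracts
  (`one_way_anova()`, `two_way_anova()`, `tukey_hsd()`, `shapiro_wilk()`,
  `pearson_cor()`).
* **A reproducible pipeline** — `run_pipeline()` chains every stage on a
  configured scene and writes TIFFs, label masks, full-precision CSVs and
  a manifest with seeds, parameters and file hashes; reruns are
  bit-identical.

## Worked example

Simulate a 256 × 256 µm field with 4 plaques, an oligomer halo
(τ = 30 µm), microglia-like cells attracted to pathology (`IBA1`,
w = 0.9) and neuron-like cells that are nearly indifferent (`NEUN`,
w = 0.1), then profile marker coverage in 3 × 30 µm rings around the
plaques:

```r
library(neuroprox)

cfg <- scene_config(
  width_px = 256, height_px = 256, pixel_size_um = 1,
  n_plaques = 4, plaque_radius_um = c(8, 14),
  oligomer_halo_tau_um = 30, n_nuclei = 30,
  cell_specs = list(
    cell_spec("IBA1", 20, soma_radius_um = 4, attraction_weight = 0.9,
              attraction_tau_um = 30),
    cell_spec("NEUN", 25, soma_radius_um = 5, attraction_weight = 0.1,
              attraction_tau_um = 100)),
  seed = 42)
sim <- simulate_scene(cfg)

rings <- build_rings(sim$truth$plaque_labels, sholl_config(), 1)
ring_coverage(rings, sim$noisy[["oligomer"]], threshold = 25)
#>   ring ring_area_um2 coverage_pct retained_fraction clipped
#> 1    1         16706    99.928170         0.8823281    TRUE
#> 2    2         17857    50.075601         0.5929800    TRUE
#> 3    3         13977     5.094083         0.3837516    TRUE
```

The oligomer halo covers essentially all of the first 30 µm ring, half of
the second and 5% of the third — the declining Sholl profile that
signals proximity to plaques. (`clipped = TRUE` warns that the rings run
off the 256-px field; `retained_fraction` says how much of each ideal ring
survives.) The marker channels tell the same story more weakly: on this
single scene `IBA1` covers 2.2 / 2.4 / 1.5 % of rings 1–3 while the
unattracted `NEUN` is flat (5.3 / 4.4 / 5.9 %); the package's tests run
exactly this contrast across 100 seeds and 6-image groups, where the
attraction difference is detected with power ≥ 0.9.

Perisomatic morphometry of the microglial channel (10 µm annulus):

```r
m <- perisomatic_morphometry(sim$truth$soma_labels, sim$noisy[["IBA1"]],
                             radius_um = 10)
head(m[m$process_area_um2 > 0, ], 3)
#>   cell_id soma_area_um2 process_length_um process_area_um2 perisomatic_radius_um
#> 1       1            49          34.97056               28                    10
#> 2       2            49          31.72792               24                    10
#> 3       3            49          34.72792               30                    10
```

Per-cell marker correlation with the conventional 4-px expansion:

```r
cell_marker_correlation(sim$truth$soma_labels,
                        channel_stack(list(IBA1 = sim$noisy[["IBA1"]],
                                           NEUN = sim$noisy[["NEUN"]])),
                        expansion_px = 4)
#> correlation_matrix: 45 cells, 4 px expansion
#>        IBA1   NEUN
#> IBA1  1.000 -0.997
#> NEUN -0.997  1.000
```

Each simulated cell expresses exactly one of the two markers, so their
per-cell means are almost perfectly anti-correlated — the expected answer
for mutually exclusive cell populations.

The statistics layer follows textbook identities exactly:

```r
one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
#>       term df sumsq meansq    F       p
#>      group  1  13.5   13.5 13.5 0.02131
#>  Residuals  4   4.0    1.0   NA      NA
```

The end-to-end demo — simulate, classify, segment, quantify, Sholl,
correlate, cluster — is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "demo_run")
```

which writes `images/`, `labels/`, `tables/` and a `manifest.yaml` with
seeds, parameters, timings and MD5 hashes of every artefact.

## Documentation

The methods vignette (`vignettes/neuroprox-methods.Rmd`) explains the
models, every tunable parameter with units and defaults, the numerical
conventions (connectivity, tie-breaking, distance snapping, skeleton
length), what the synthetic scenes do and do not emulate, and known
limitations.
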
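---
title: "Mapping zones of cancer nuclear morphological diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping zones of cancer nuclear morphological diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-grade serous ovarian carcinoma (HGSOC) and other solid tumors show
striking regional variation in cancer-cell nuclear morphology. A tumor
region where cancer nuclei *diversify in shape* — become heterogeneously
irregular rather than uniformly round — is a candidate marker of local
selective pressure and disease aggressiveness. `morphozone` detects such
regions from the single-cell tables that modern H&E image-analysis
pipelines produce: one row per cell with its centroid, class
(cancer / stromal / lymphocyte) and nuclear area and perimeter. The
package deliberately starts *after* segmentation and classification;
no pixel data are touched.

## The procedure

1. **Tissue polygon and zone count.** The tissue footprint is the convex
   hull of all cell centroids. The number of Voronoi seeds scales with
   the square root of the tissue area, `N = floor(sqrt(A') / 3)` with
   `A' = area / area_unit_scale`, so spatial resolution tracks tissue
   size rather than cellularity: a fibrotic, cancer-poor tumor is not
   penalised with coarse zones.
2. **Tessellation.** `N` cancer cells are drawn uniformly at random as
   seeds; every cell joins the zone of its nearest seed (Euclidean
   distance, ties to the smaller seed cell id). Seeding on cancer cells
   guarantees at least one cancer cell per zone and puts more zones
   where cancer cells are dense.
3. **Zonal shape variability.** Each nucleus gets a shape factor
   `s = p / (2 * sqrt(pi * a))` — 1 for a circle, larger for irregular
   outlines. A zone's statistic `Y` is the *sample standard deviation*
   of `s` over its cancer cells.
4. **Spatial test.** On the queen-contiguity graph of zone polygons
   (neighbors share an edge or a point), the local Moran statistic
   `I_i = (Y_i - Ybar) * sum_j w_ij (Y_j - Ybar)` is standardised by
   its conditional-randomization moments and referred to the standard
   normal; a Monte-Carlo (Hope) alternative is available. P-values are
   Benjamini–Hochberg-adjusted within the slide.
5. **Calls.** A zone is *diversified* when `q < alpha` and `Y` exceeds
   the slide mean; a slide is *positive* when at least one zone is
   diversified.

## The null model and the analytic moments

Significance is assessed under *conditional randomization*: zone `i`'s
value is held fixed and the other zones' values are permuted. With
binary weights the neighbor sum is then the total of a simple random
sample of size `w_i` (the zone's degree) drawn without replacement
from the remaining deviations, which gives closed forms

    E[I_i]   = -w_i (Y_i - Ybar)^2 / (n - 1)
    Var[I_i] = (Y_i - Ybar)^2 w_i s2_i (n - 1 - w_i) / (n - 2)

where `s2_i` is the population variance of the other zones'
deviations. The test suite verifies both against 50,000 actual
conditional permutations; this oracle equivalence is the package's
central correctness property. Whether to then use the normal reference
or the permutation p is a real choice: at a few hundred zones per slide
and approximately Gaussian `Y` the two agree closely (the suite checks
median disagreement < 0.03 at 200 zones and > 95% agreement of calls at
`alpha = 0.05`), but with few zones or heavily skewed `Y` the
permutation p is the safer route, which is why both are exposed via
`div_params(p_source = )`.

## The reference mean

The statistic needs a reference mean `Ybar`. The conventional local
Moran uses the **global** mean of `Y`, and that is the default. A
zone-specific **neighborhood** mean is also offered, with one subtlety:
taken over the neighbors alone the lag term would vanish identically
(deviations of a set from its own mean sum to zero), so the
neighborhood variant uses the *closed* neighborhood — the zone together
with its neighbors. Analytic moments are only derived for the global
mode; the neighborhood mode always uses the permutation p.

## Direction of the test and the call rule

The test is two-sided by default: a high-variability zone can be
significant either as part of a high cluster (positive `I`) or as a
spatial outlier against low neighbors (negative `I`). Both are
biologically meaningful diversification patterns, so the call rule
requires only significance *plus* `Y_i` above the slide mean — the
second condition stops significantly *low*-variability zones (uniform
nests inside heterogeneous surroundings) from being called diversified.
`flag_rule = "significant_any"` drops the second condition.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `area_unit_scale` | 1 um^2/unit | unit of area entering the seed-count rule. The square-root rule is not dimensionless and the calibration that reproduces a given mean zone count per slide depends on the cohort's coordinate units; the parameter is exposed for exactly that reason. |
| `min_cancer_cells_per_zone` | 2 | below this a standard deviation is undefined or worthless; such zones are excluded and **removed** from the weights graph (their neighbors are not bridged through them). |
| `alpha` | 0.05 | level applied to the BH-adjusted p within each slide. |
| `tail` | two_sided | see above. |
| `p_source` | analytic | `permutation` switches to the Hope estimator `p = (1 + #extreme) / (1 + B)`, bounded below by `1/(1+B)`. |
| `n_permutations` | 999 | permutations per zone for the Hope p. |
| queen contact `tol` | 1e-6 um | polygon contact tolerance; sub-nanometre, far below any biological scale but safely above double rounding of clip-intersection vertices at slide-scale coordinates. |

## The synthetic world

`simulate_slide()` emulates the inputs the detector expects, with known
ground truth:

* **Counts and extent.** 20,000 cancer cells, 3,800 lymphocytes and
  4,300 stromal cells on a 5 x 5 mm slide — the class proportions of
  large H&E cohorts scaled down by roughly an order of magnitude so a
  full run takes seconds.
* **Positions.** A Thomas cluster process fitted to exact counts
  (Poisson parents at `2e-6 / um^2`, Gaussian dispersion 150 um),
  mimicking nests and aggregates; `"uniform"` is available as a
  degenerate control.
* **Morphology.** `s = 1 + exp(N(log 0.15, 0.35))`, i.e. `s - 1`
  lognormal: median shape factor about 1.15, guaranteed `s >= 1`.
  Nuclear area is lognormal with median 40 um^2; the perimeter is
  **back-computed** as `p = s * 2 * sqrt(pi * a)` so each cell's true
  shape factor is exact rather than approximately recovered.
* **Planted zones.** Circles (default three, radius 250 um) inside
  which the Gaussian sd of `log(s - 1)` is multiplied by
  `variance_multiplier` (default 3) — the *spread* of the shape factor
  is inflated, not its mean, because the detection statistic is a
  standard deviation. A mean shift would be a different (and easier)
  signal; it can be emulated separately by shifting
  `base_logshape_mean`. Optionally lymphocytes inside a circle are
  thinned with probability `lymphocyte_depletion`. Class counts match
  the config exactly *before* thinning.

What a green recovery test does establish: on clustered point patterns
with a threefold variance inflation confined to circles much larger
than a zone, the pipeline finds the circles (sensitivity >= 0.7,
specificity >= 0.9 at the default configuration) and controls the
false-flag rate on null slides. What it does not establish: robustness
to segmentation error, stain artefacts, mis-classification of cell
types, or non-circular diversification geometries — none of which the
generator simulates.

## Numerical and degenerate-input choices

* `SD` is the sample standard deviation (n − 1): unbiased variance at
  the small per-zone counts where it matters.
* Voronoi cells are built by incremental half-plane clipping against
  the convex tissue polygon, visiting competitors nearest-first and
  stopping once no further bisector can cut; the construction was
  cross-checked against an independent Dirichlet tessellation
  implementation (tile areas and edge adjacency agree exactly on a
  rectangular window).
* Unbounded Voronoi cells are clipped to the tissue hull so every zone
  has a finite polygon, area and adjacency.
* Duplicate seed coordinates are rejected, not jittered —
  reproducibility over convenience.
* Distance ties in cell assignment go to the seed with the smaller
  cell id: deterministic and independent of seed order.
* Zones whose conditional variance vanishes (isolated zones, or all
  other `Y` equal) are excluded with an explicit reason rather than
  given an arbitrary p.
* Fisher's exact test, Kruskal–Wallis and BH adjustment are delegated
  to R's `stats`; the Jonckheere–Terpstra trend test (half-counted
  ties, tie-corrected variance, permutation option) is implemented in
  the package and verified against exhaustive enumeration.
* In the Jonckheere test the alternative describes the trend along the
  factor's level order. `zonal_groups()` orders its factor
  `rest < adjacent < diversified` so the default `"decreasing"`
  alternative tests depletion toward the diversified zones.

## Known limitations

* Only convex-hull tissue outlines: `alpha_shape` is reserved in the
  interface but not implemented, so strongly concave sections or
  multi-fragment biopsies get an over-generous footprint (and hence
  somewhat more seeds than ideal).
* The seed-count rule's absolute calibration (zones per slide for a
  given cohort) is left to `area_unit_scale`; no single default can
  reproduce a particular cohort's mean zone count without knowing its
  units and typical tissue areas.
* Sample-level association statistics (`fisher_exact_2x2`,
  `kruskal_wallis`, `microenv_subtype`, `build_contingency`) operate on
  per-slide summaries; survival modelling is out of scope.
* The package is an S3 "one fitting function + methods" design:
  `detect_zones()` returns a classed object with `print`, `summary`,
  `plot` and `as.data.frame` methods. `coef`/`predict`/`residuals`
  methods are deliberately absent — the procedure estimates no
  parameters and predicts nothing; simulation lives in
  `simulate_slide()`, which is a first-class, tested generator rather
  than a method of the fit.

## A minimal session

```{r, eval = FALSE}
library(morphozone)

cfg <- slide_config(rng_seed = 1)        # desk-scale defaults
sim <- simulate_slide(cfg)
fit <- detect_zones(sim$cells, seed = 1)
summary(fit)
plot(fit)

truth <- match_zones_to_truth(fit$zone_map, sim$truth, sim$cells)
recovery_metrics(fit$results$diversified, unname(truth))

comp <- zone_composition(fit$zone_map, sim$cells)
grp  <- zonal_groups(fit$results$diversified, fit$weights)
jonckheere_test(comp$lymphocyte_fraction, grp, alternative = "decreasing")
```
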
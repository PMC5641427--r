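# spermshape

Outline-based geometric morphometrics of sperm head contours in R.

Mouse sperm heads are falciform — a hooked, tapered blade — and their
fertilizing ability correlates with how *thin* the head is. Classical
manual measurements (hand-picked length, width, angle landmarks) are noisy
and miss most of the outline. This package implements the quantitative
alternative: the whole closed head contour is encoded as elliptic Fourier
descriptors (EFD), normalized so that shape comparison is independent of
position, size, rotation and digitization start point, and the normalized
coefficient space is analyzed by PCA. The first-harmonic aspect ratio
(minor/major axis of the best-fitting ellipse, the coefficient `d1`) falls
out of the normalization as a single dimensionless thinness indicator.

It is written for reproductive-biology labs quantifying sperm morphology
from nucleus-stained micrographs, and more generally for anyone doing
outline morphometrics on chain-coded or polygonal 2D shapes.

## The model

A closed contour is parameterized by arc length `t` over one period `T`
and expanded as

    X(t) = sum_n  a_n cos(2 n pi t / T) + b_n sin(2 n pi t / T)
    Y(t) = sum_n  c_n cos(2 n pi t / T) + d_n sin(2 n pi t / T)

for harmonics `n = 1..N` (default `N = 20`). Coefficients are estimated by
the classical closed-form line integrals over the polygon segments.
Normalization removes the starting-point phase and the orientation of the
first-harmonic ellipse and divides out its semi-major magnitude, fixing
`a1 = 1, b1 = 0, c1 = 0`; the remaining `4N - 3 = 77` free parameters
(`d1`, then `a2, b2, c2, d2, ...`) form the shape vector. `d1 ∈ (0, 1]` is
the aspect ratio of the first-harmonic ellipse: low `d1` = thin head.

On top of that sit:

* **Segmentation** — Otsu discriminant-analysis binarization and
  Moore-neighbor boundary tracing of 8-connected components into Freeman
  chain codes (with a plain-text `.chc` reader/writer);
* **PCA** — covariance PCA of the shape vectors with contribution rates,
  factor loadings (biplot arrow lengths), mean ± 2 SD shape
  reconstruction along any component, and a two-pass abnormality filter
  that excludes specimens with pass-1 PC1 score > 0.55 before refitting;
* **Measurements** — absolute major/minor axes, the antero-posterior (AP)
  axis (longest chord), its angle θ to the major axis, head area, and
  coefficients of variation;
* **Group statistics** — pooled/Welch t, F, Kolmogorov–Smirnov and
  Shapiro–Wilk tests, percent differences against a declared reference
  group, and an all-pairs Steel–Dwass nonparametric comparison
  (tie-corrected rank sums referred to the studentized range);
* **A synthetic generator** — populations of hook-shaped head contours
  (and rendered 8-bit images) whose aspect-ratio mean, CV, and abnormal
  admixture are planted exactly, for validating every stage against known
  ground truth.

## Worked example

Two synthetic strains, 150 heads each, with a 5.7 % thinner mean aspect
ratio planted in the second (0.4715 vs 0.500) and CV 5.3 % in both:

```r
library(spermshape)
b6n  <- sample_population(population_spec(150, mean_aspect = 0.500,  cv_aspect = 0.053,
                                          rng_seed = 1, group_label = "b6n"))
bdf1 <- sample_population(population_spec(150, mean_aspect = 0.4715, cv_aspect = 0.053,
                                          rng_seed = 2, group_label = "bdf1"))
res <- run_pipeline(c(b6n, bdf1), reference_group = "b6n")
#> stage efd: 300 specimens, 77 coefficients
#> stage filter: 300 in, 0 excluded (PC1 > 0.55), 300 out
#> stage measure: 300 specimens
#> stage statistics: 2 groups, reference 'b6n'

res$statistics$summary[, c("group", "n", "mean", "cv_percent", "percent_diff_vs_ref")]
#>   group   n  mean cv_percent percent_diff_vs_ref
#> 1   b6n 150 0.501       4.79                0.00
#> 2  bdf1 150 0.472       5.91                5.61

subset(res$statistics$tests, test_name == "t-test")[, c("group1", "group2", "p_value", "significance_label")]
#>   group1 group2  p_value significance_label
#> 1    b6n   bdf1 1.09e-18                ***

res$filter$pass2
#> EFD PCA: 300 specimens, 77 coefficients
#>   contribution rates: PC1 20.5%, PC2 13.3%, PC3 12.3%, PC4 9.7%, PC5 8.4%
```

The recovered percent difference (5.61 % here, one seed) scatters around
the planted 5.7 % with a per-seed standard error of about 0.6 points; the
one-tailed pooled t-test is significant at the *** level. No specimen
crosses the abnormality threshold in these clean populations; add
`abnormal_fraction = 0.1` to `population_spec()` to watch the pass-1 PC1
filter pick the planted outliers out again.

The `analysis/` directory holds the same workflow as five numbered,
narrated scripts (simulate → trace images → EFD + PCA → measurements →
group statistics), each writing its tables under `results/tables/`:

```sh
Rscript analysis/01_simulate.R     # populations + ground truth
Rscript analysis/02_trace.R        # raster → Otsu → chain codes round trip
Rscript analysis/03_efd_pca.R      # coefficients, abnormality filter, PCA
Rscript analysis/04_measurements.R # axes, theta, areas, CVs
Rscript analysis/05_group_stats.R  # percent differences and tests
```

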
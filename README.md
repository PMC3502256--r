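# periband

Quantitative analysis of the host response around knitted surgical mesh
implants, for biomaterials and tissue-engineering groups evaluating mesh
biocompatibility in animal explant studies.

When a polymer mesh is implanted, inflammatory cells (CD45⁺ leukocytes,
CD68⁺ macrophages) accumulate against the filament surface while new
tissue (Sirius-red collagen, αSMA⁺ myofibroblasts, CD31⁺ vessels) forms
throughout the implant bed. periband turns stained micrographs, tensile
records and necropsy measurements into the study's standard statistics:

* **Peri-filament band histomorphometry** — segment mesh filament
  bundles in brightfield or fluorescence micrographs, draw concentric
  distance bands of width Δ = 50 µm around the filament surface with an
  exact Euclidean distance transform (band *b* holds the tissue pixels
  with (b−1)Δ < d ≤ bΔ), and measure per-band positive-stain area
  fractions

  fraction_b = |positive ∩ band_b ∩ tissue| / |band_b ∩ tissue|,

  plus the whole-image fraction. A *diminishing gradient* of staining
  with distance — the foreign-body-reaction signature — is tested with a
  Kruskal–Wallis omnibus across bands, Bonferroni-corrected pairwise
  rank comparisons, and a Spearman trend filter.
* **Explant biomechanics** — load–elongation curves are trimmed at the
  100 mN pre-load, strain is 100·x/L₀ (L₀ = 14 mm gauge length), group
  curves are averaged with pointwise Student-t 95% envelopes, and the
  toe/linear shape is fitted by continuous segmented least squares
  (load ~ 1 + x + (x−c)₊, breakpoint c minimising the RSS); the linear
  slope (N/mm) is the headline stiffness.
* **Outcome statistics** — mesh contraction, adhesion area and weight
  gain arithmetic, and a group-comparison engine: D'Agostino–Pearson
  normality report, tie-corrected Kruskal–Wallis, pairwise two-sided
  rank-sum tests with Bonferroni correction.
* **Synthetic data with ground truth** — micrographs whose stain
  positivity decays with distance d from the filament surface as
  p(d) = floor + (p0 − floor)·e^(−d/λ), bilinear tensile curves, and
  Gaussian outcome tables, all seeded; every downstream stage is tested
  against this truth.

## Worked example

Simulate a CD68-like field (stain concentrated at the filaments), run the
measurement chain, and test the gradient:

```r
library(periband)
library(tibble)

scene <- histology_scene(
  filaments = bundle_layout(1, 3, width_um = 512, height_um = 512),
  stain_mode = "brightfield_dab",
  p0 = 0.8, lambda_um = 50, floor = 0.05, noise_sd = 0.02)
sim <- generate_histology(scene, seed = 1)

fil     <- binarize_filaments(sim$image)
bundles <- label_bundles(fil, px_size_um = 2)
bands   <- build_bands(bundles, increment_um = 50, n_bands = 4)
pos     <- positive_mask(sim$image, "dab", filament_mask = fil)
prof    <- band_fractions(bands, pos, tissue = !fil)
as_tibble(prof)
#> # A tibble: 4 × 6
#>    band band_lo_um band_hi_um tissue_px positive_px fraction
#>   <int>      <dbl>      <dbl>     <int>       <int>    <dbl>
#> 1     1          0         50     10027        5065   0.505
#> 2     2         50        100     13626        3072   0.225
#> 3     3        100        150     17537        2033   0.116
#> 4     4        150        200     13392        1020   0.0762
```

Half the tissue within 50 µm of the filaments is stain-positive, falling
to 8% at 150–200 µm; the measured fractions track the generator's decay
truth. Across 6 animals × 4 fields the gradient test:

```r
profiles <- simulate_gradient_profiles(scene, n_animals = 6,
                                       images_per_animal = 4, seed = 2)
gradient_test(profiles)
#> <gradient_result> Kruskal-Wallis H = 21.600 (df = 3), p = 7.9e-05; Spearman rho = -0.97
#> Diminishing gradient declared.
```

Strain and stiffness:

```r
strain_percent(0.9, 14)   # 0.9 mm elongation at 14 mm gauge -> 6.4 % strain
#> [1] 6.4
strain_percent(2.0, 14)
#> [1] 14

cv <- generate_tensile(tensile_truth(0.5, 5.0, 1.7, noise_sd_N = 0.05),
                       n_points = 100, max_elongation_mm = 4, seed = 3)
fit_bilinear(trim_preload(cv))
#> <bilinear_fit> toe 0.526 N/mm, linear 5.01 N/mm, breakpoint 1.51 mm (RSS 0.167)
```

The fitted toe and linear slopes recover the generating 0.5 and
5.0 N/mm; the breakpoint is 1.51 mm in post-trim coordinates because the
pre-load trim re-zeroes elongation 0.2 mm into the toe (0.1 N / 0.5 N/mm).
`tidy()`, `glance()` and `autoplot()` methods cover every result type,
and `run_pipeline(default_run_config())` chains all stages end to end.

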
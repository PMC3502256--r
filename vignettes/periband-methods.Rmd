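---
title: "Methods: peri-filament band histomorphometry and explant biomechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-filament band histomorphometry and explant biomechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periband)
```

## The problem

Knitted polymer meshes implanted to reinforce weakened tissue provoke a
foreign-body reaction: leukocytes (CD45) and macrophages (CD68) accumulate
against the filament surface, while new tissue — collagen (Sirius red),
myofibroblasts (αSMA) and vessels (CD31) — forms throughout the implant
bed. Two quantitative questions follow from stained sections and from
tensile tests of explants:

1. *How is staining distributed with distance from the mesh filaments?*
   periband answers this by segmenting filament bundles, drawing
   concentric distance bands of fixed width (50 µm by default) around the
   filament surface, and measuring the positive-stain area fraction per
   band. A nonparametric test then asks whether the fractions diminish
   with distance.
2. *How stiff is the explanted mesh-tissue composite?* periband trims
   load–elongation records at the pre-load, converts elongation to strain
   relative to the gauge length, averages curves with pointwise 95%
   confidence envelopes, and characterises the toe/linear shape by a
   segmented least-squares fit.

A third component handles per-animal outcomes (mesh contraction, adhesion
area, weight gain, ordinal adhesion scores) with the Kruskal–Wallis test
and Bonferroni-corrected pairwise rank comparisons.

## Band quantification

The geometric core is an exact Euclidean distance transform from the
union of all filament pixels (EBImage's `distmap`, which we verified
bit-identical to per-pixel brute-force enumeration). Distances are
between pixel centres, scaled by the pixel size in µm. Band $b$ collects
tissue pixels with

$$(b-1)\,\Delta < d \le b\,\Delta, \qquad \Delta = 50\ \mu m,$$

a half-open convention so that every non-filament pixel within range has
exactly one band. With several bundles, each pixel is binned by its
distance to the *nearest* filament pixel of any bundle — a single union
transform — so no tissue is double-counted where annuli of two bundles
would overlap. Bands may be truncated by the image border; a band with no
tissue pixels is reported as missing rather than zero. The per-band
statistic is

$$\mathrm{fraction}_b = \frac{|\mathrm{positive} \cap \mathrm{band}_b \cap \mathrm{tissue}|}{|\mathrm{band}_b \cap \mathrm{tissue}|},$$

and the whole-image fraction uses all tissue pixels. Filament interiors
are excluded from every denominator; whether the original workflow did so
is unknowable from the text, so this is a package decision, flagged for
sensitivity analysis (including them changes the denominator by the
filament area fraction).

Inflammatory markers (CD45, CD68) are analysed *near the filament* — the
0–50 µm band is the headline statistic — because the foreign-body
response concentrates at the material surface; neotissue markers (Sirius
red, αSMA, CD31) show no continuous gradient and use the whole-image
fraction (`analysis_mode()` encodes this mapping).

### Stain positivity

* **DAB (brown chromogen):** RGB optical densities are unmixed with the
  standard published haematoxylin/DAB stain vectors (colour
  deconvolution), and the DAB density is thresholded by Otsu.
* **Sirius red:** red-dominance ratio $R/(R+G+B)$, Otsu threshold.
* **Fluorescence:** Otsu on the intensity channel.

Thresholds are estimated over non-filament pixels; a stain signal with
dynamic range below `min_range` (default 0.02) yields an empty mask, so a
stain-free image does not produce threshold noise. Otsu on a genuinely
unimodal-but-noisy signal can still split noise; the generator-based
tests quantify this (Jaccard ≥ 0.85 against truth at the noise levels
tested).

### Filament segmentation

Micrograph luminance typically holds three classes — near-black filament
cross-sections, mid-tone stain, light tissue (fluorescence inverts this:
signal-void filament, dim tissue, bright marker). A single Otsu threshold
can land between stain and tissue, so the filament class is the lowest
class of an exhaustive two-threshold (three-class) Otsu partition,
accepted only if its mean intensity is ≤ `dark_max` (default 0.2). The
mask is cleaned by a 3 px disc opening and hole filling. Hole filling
also fills the interstice enclosed by a ring of touching monofilaments;
we treat that interstice as bundle interior, which is what band
construction around a *bundle* wants. Bundles are then labelled on the
mask after a morphological closing of radius `merge_radius_um` (default
30 µm — monofilaments within one knitted yarn nearly touch, separate
yarns do not), with 8-connected components and a minimum bundle area of
1000 µm². Fields are framed on the most central bundles, so
`select_central_bundles()` keeps the `k = 4` bundles whose centroids are
nearest the image centre (Euclidean distance, ties broken by label id).

### The gradient test

The per-animal unit entering statistics is the mean band fraction over
that animal's analysed fields (4 per animal by default, 6 animals per
group). `gradient_test()` runs a tie-corrected Kruskal–Wallis omnibus
across band indices, all pairwise two-sided rank-sum comparisons with
Bonferroni correction (m = number of pairs), and a Spearman trend; a
*diminishing gradient* is declared when the omnibus p < 0.05 and the
trend is negative. The trend filter halves the nominal false-positive
rate on flat profiles, since a flat truth produces a negative trend only
half the time. With all fractions identical the omnibus is reported as
H = 0, p = 1 by convention (the rank statistic is undefined under total
ties).

## Biomechanics

Records are trimmed where the load first reaches the 100 mN pre-load
(linear interpolation of the crossing, which becomes the new elongation
origin), and after the peak load (specimen failure). Strain is
$100 \cdot x / L_0$ with $L_0 = 14$ mm gauge length, reported to 2
significant figures. Averaged curves interpolate each record linearly
onto a common grid and use Student-t pointwise 95% intervals with
$n - 1$ df; two groups differ significantly where their envelopes are
disjoint, and the sustained-separation onset is the smallest grid point
from which every later point separates.

The toe/linear fit is continuous segmented least squares: for each
candidate breakpoint $c$ on the sample grid, regress load on
$\{1, x, (x-c)_+\}$ and keep the $c$ minimising the residual sum of
squares, then polish $c$ by 1-D continuous optimisation between its grid
neighbours (so a noiseless bilinear curve whose breakpoint falls between
samples is still recovered to numerical precision). When the two slopes
differ by less than 5% (relative), the curve is flagged as having no
distinct toe region. The fitted *linear slope* is the headline stiffness.

A note on identifiability: recovering both slopes to a few percent
requires that each segment carries enough leverage relative to the load
noise. The validation suite therefore uses a balanced truth (toe
1.0 N/mm, linear 3.0 N/mm — the ≈3× stiffening seen between early and
late explants — breakpoint at 70% of a 4 mm record) for its noisy
recovery checks; with a short, shallow toe the toe-slope standard error
exceeds any reasonable tolerance at 2% load noise, for any estimator.

## Outcome statistics

Mesh contraction treats "size" as area (length × width):
$100(1 - A_{explant}/A_{original})$; a linear-dimension mode
($100(1 - \overline{d_{explant}/d_{original}})$) is available behind a
flag because the defining text is ambiguous. Adhesion area is a plain
percentage of mesh area; weight gain is per-animal change from baseline
(absolute or relative). `compare_groups()` reports a per-group
D'Agostino–Pearson normality check (implemented from the published
skewness and kurtosis Z transformations because no installed R package
provides this omnibus test; it requires n ≥ 8 and is reported, not
gating), the tie-corrected Kruskal–Wallis omnibus, and pairwise two-sided
rank-sum tests with Bonferroni multiplier equal to the number of pairs
actually compared (10 for 5 groups). Ordinal adhesion scores enter the
same rank-based engine unchanged.

## The synthetic-data generator

No micrographs or tensile records are deposited with the source study,
so the generator provides inputs with known truth:

* **Micrographs** (`histology_scene()`, `generate_histology()`):
  filament bundles are rings of touching 50 µm-radius circles (100 µm
  monofilament diameter); each tissue pixel is stain-positive with
  probability $p(d) = \mathrm{floor} + (p_0 - \mathrm{floor})
  e^{-d/\lambda}$, distance measured by the same pixel-centre convention
  the measurement uses. Defaults $p_0 = 0.8$, floor $= 0.05$,
  $\lambda = 50\ \mu m$ give a strong surface-concentrated infiltrate;
  $\lambda = \infty$ gives the distance-independent stains. Rendering is
  Beer–Lambert with the same H-DAB vectors the deconvolution uses, a
  red/pale palette for Sirius red, or a single fluorescence channel;
  Gaussian intensity noise is clipped to [0, 1]. By default the whole
  image is tissue ∪ filament (zero background margin).
* **Tensile curves** (`tensile_truth()`, `generate_tensile()`): exact
  bilinear load with additive Gaussian load noise on a strictly
  increasing elongation grid.
* **Outcome tables** (`generate_group_table()`): Gaussian cells with per
  group × timepoint location and scale, 6 animals per cell by default.

All three are deterministic under a fixed seed. What the generator does
*not* emulate: real stain texture and uneven illumination, partial
filaments at image borders, folded or sectioned-oblique filaments,
vessel/cell morphology (positivity is pixelwise Bernoulli, spatially
uncorrelated given distance), and heavy-tailed biological outcome
distributions. Passing tests therefore demonstrate correctness of the
*measurement chain and statistics given the stated model*, not robustness
to every real-world artefact.

## Problem sizes and numerical choices

Simulation-based checks in the test-suite and acceptance script use:
224×224 px scenes at 2 µm/px (one 3-filament bundle) with 6 animals × 4
fields and 200 replicates for gradient power/size; 100-point curves and
200 replicates for bilinear recovery and CI coverage; 50 random rasters
up to 64×64 px for the exhaustive band-geometry oracle. The gradient
replicates reuse one distance transform per scene
(`simulate_gradient_profiles()`), which is mathematically identical to
generating each field image and is verified against the image-by-image
path in the tests. Degenerate inputs are explicit results, not crashes:
blank images return a no-filament mask, stain-free images an empty
positive mask, all-tied statistics H = 0 / p = 1, constant curves and
too-few samples are errors with clear messages.

## Known limitations

* Brightfield positivity assumes the standard published stain vectors;
  batch-specific restaining would need vector re-estimation, which is not
  implemented.
* The bundle merge radius is a geometric proxy for "same yarn"; unusually
  tight mesh knits could merge adjacent yarns.
* The gradient test treats bands as independent samples across animals
  and ignores within-animal correlation across bands; with 4 bands × 6
  animals this is conservative in the direction of the trend filter but
  not exact.
* Cell counting, collagen fibre orientation and packing density, and
  vessel morphometry are out of scope: the unit of measurement is
  stained *area*.
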
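test_that("a lone filament pixel yields the textbook band geometry", {
  # pixel size 50 um: the 4 axial neighbours sit at exactly d = 50 um
  # (band 1, half-open upper bound), diagonals at 50*sqrt(2) (band 2)
  mask <- matrix(FALSE, 65, 65)
  mask[33, 33] <- TRUE
  bands <- build_bands(mask, increment_um = 50, n_bands = 4,
                       px_size_um = 50)
  expect_equal(bands$bands[33, 33], 0L)
  axial <- c(bands$bands[32, 33], bands$bands[34, 33],
             bands$bands[33, 32], bands$bands[33, 34])
  expect_equal(axial, rep(1L, 4))
  diagonal <- c(bands$bands[32, 32], bands$bands[32, 34],
                bands$bands[34, 32], bands$bands[34, 34])
  expect_equal(diagonal, rep(2L, 4))
})

test_that("an increment beyond the image diagonal puts everything in band 1", {
  mask <- matrix(FALSE, 64, 64)
  mask[40, 22] <- TRUE
  bands <- build_bands(mask, increment_um = 1e5, n_bands = 1, px_size_um = 2)
  expect_true(all(bands$bands[!mask] == 1L))
})

test_that("bands from multiple bundles use the union distance transform", {
  set.seed(10)
  for (i in 1:5) {
    n <- sample(20:64, 1)
    mask <- matrix(FALSE, n, n)
    mask[sample(n * n, 3)] <- TRUE
    bands <- build_bands(mask, increment_um = 12, n_bands = 3, px_size_um = 3)
    expect_identical(bands$bands, bf_band_labels(mask, 3, 12, 3L))
  }
})

test_that("every non-filament pixel within range has exactly one band label", {
  set.seed(99)
  mask <- matrix(runif(48 * 48) < 0.02, 48, 48)
  mask[5, 5] <- TRUE
  bands <- build_bands(mask, increment_um = 20, n_bands = 3, px_size_um = 4)
  d <- bf_distance_um(mask, 4)
  in_range <- !mask & d <= 60
  expect_true(all(bands$bands[in_range] >= 1))
  expect_true(all(bands$bands[!mask & d > 60] == -1L))
  # disjointness is structural (one label per pixel); check the interval
  for (b in 1:3) {
    sel <- bands$bands == b
    expect_true(all(d[sel] > (b - 1) * 20 & d[sel] <= b * 20))
  }
})

test_that("band fractions equal per-pixel counting on a hand raster", {
  mask <- matrix(FALSE, 20, 20)
  mask[10, 10] <- TRUE
  bands <- build_bands(mask, increment_um = 3, n_bands = 4, px_size_um = 1)
  tissue <- !mask
  positive <- matrix(FALSE, 20, 20)
  positive[c(10, 11, 13), c(11, 12)] <- TRUE # hand-placed positives
  prof <- band_fractions(bands, positive, tissue)
  bf <- bf_band_labels(mask, 1, 3, 4L)
  for (b in prof$band) {
    t_cnt <- sum(bf == b & tissue)
    p_cnt <- sum(bf == b & tissue & positive)
    expect_identical(prof$tissue_px[prof$band == b], t_cnt)
    expect_identical(prof$positive_px[prof$band == b], p_cnt)
    expect_identical(prof$fraction[prof$band == b], p_cnt / t_cnt)
  }
  expect_equal(attr(prof, "whole_fraction"),
               sum(positive & tissue) / sum(tissue))
})

test_that("degenerate positive masks give all-one or all-zero fractions", {
  mask <- matrix(FALSE, 30, 30); mask[15, 15] <- TRUE
  bands <- build_bands(mask, increment_um = 10, n_bands = 2, px_size_um = 2)
  tissue <- !mask
  full <- band_fractions(bands, tissue, tissue)
  expect_true(all(full$fraction == 1))
  expect_equal(attr(full, "whole_fraction"), 1)
  none <- band_fractions(bands, matrix(FALSE, 30, 30), tissue)
  expect_true(all(none$fraction == 0))
  expect_equal(attr(none, "whole_fraction"), 0)
  expect_error(band_fractions(bands, tissue, matrix(FALSE, 30, 30)),
               "no tissue")
})

test_that("zero-tissue bands are missing, not zero", {
  mask <- matrix(FALSE, 64, 64); mask[32, 32] <- TRUE
  # 6 bands of 50 um at 2 um/px: the farthest pixel is ~90 um away, so
  # bands 3..6 hold no pixels at all
  bands <- build_bands(mask, increment_um = 50, n_bands = 6, px_size_um = 2)
  prof <- band_fractions(bands, matrix(FALSE, 64, 64), !mask)
  expect_true(all(prof$tissue_px > 0))
  expect_lt(nrow(prof), 6L)
})

test_that("fractions are invariant to translation and 90-degree rotation", {
  sc <- default_test_scene(n_px = 128, px = 4)
  sim <- generate_histology(sc, seed = 21)
  measure <- function(fil, pos, tis) {
    bands <- build_bands(fil, increment_um = 50, n_bands = 2, px_size_um = 4)
    band_fractions(bands, pos, tis)$fraction
  }
  base <- measure(sim$truth$filament, sim$truth$positive, sim$truth$tissue)
  rot <- function(m) t(m)[, nrow(m):1]
  expect_equal(measure(rot(sim$truth$filament), rot(sim$truth$positive),
                       rot(sim$truth$tissue)), base)
  shift <- function(m, k = 7) {
    out <- matrix(FALSE, nrow(m) + k, ncol(m) + k)
    out[(k + 1):(k + nrow(m)), (k + 1):(k + ncol(m))] <- m
    out
  }
  # translation with padding marked non-tissue leaves fractions unchanged
  expect_equal(measure(shift(sim$truth$filament), shift(sim$truth$positive),
                       shift(sim$truth$tissue)), base)
})

test_that("whole-image fraction is the tissue-weighted mean over regions", {
  sc <- default_test_scene(n_px = 128, px = 4)
  sim <- generate_histology(sc, seed = 31)
  bands <- build_bands(sim$truth$filament, increment_um = 50, n_bands = 2,
                       px_size_um = 4)
  prof <- band_fractions(bands, sim$truth$positive, sim$truth$tissue)
  beyond <- bands$bands == -1L & sim$truth$tissue
  total_t <- sum(prof$tissue_px) + sum(beyond)
  total_p <- sum(prof$positive_px) + sum(beyond & sim$truth$positive)
  expect_equal(attr(prof, "whole_tissue_px"), total_t)
  expect_equal(attr(prof, "whole_fraction"), total_p / total_t)
})

test_that("positive mask recovers the truth stain for every chemistry", {
  cases <- list(
    list(mode = "brightfield_dab", marker = "dab"),
    list(mode = "brightfield_sirius", marker = "sirius_red"),
    list(mode = "fluorescence", marker = "fluor")
  )
  for (cs in cases) {
    sc <- default_test_scene(stain_mode = cs$mode, noise_sd = 0)
    sim <- generate_histology(sc, seed = 4)
    pos <- positive_mask(sim$image, cs$marker,
                         filament_mask = sim$truth$filament)
    expect_identical(as_plain(pos), sim$truth$positive)
    # moderate noise: high overlap remains
    scn <- default_test_scene(stain_mode = cs$mode, noise_sd = 0.04)
    simn <- generate_histology(scn, seed = 5)
    posn <- positive_mask(simn$image, cs$marker,
                          filament_mask = simn$truth$filament)
    expect_gte(jaccard(as_plain(posn), simn$truth$positive), 0.85)
  }
})

test_that("a stain-free image yields an empty positive mask", {
  sc <- default_test_scene(p0 = 0, floor = 0, noise_sd = 0)
  sim <- generate_histology(sc, seed = 6)
  pos <- positive_mask(sim$image, "dab", filament_mask = sim$truth$filament)
  expect_false(any(pos))
  expect_error(positive_mask(sim$image, "fluor"), "expects")
})

test_that("markers map to their analysis mode", {
  expect_equal(analysis_mode("cd68"), "near_filament")
  expect_equal(analysis_mode("CD45"), "near_filament")
  expect_equal(analysis_mode("cd31"), "whole_image")
  expect_equal(analysis_mode("sirius"), "whole_image")
  expect_equal(analysis_mode("asma"), "whole_image")
  expect_error(analysis_mode("xyz"), "unknown marker")
})

test_that("headline fraction follows the marker's analysis mode", {
  sc <- default_test_scene()
  sim <- generate_histology(sc, seed = 8)
  bands <- build_bands(sim$truth$filament, px_size_um = sc$px_size_um)
  prof <- band_fractions(bands, sim$truth$positive, sim$truth$tissue)
  expect_equal(headline_fraction(prof, "cd68"),
               prof$fraction[prof$band == 1])
  expect_equal(headline_fraction(prof, "cd31"),
               attr(prof, "whole_fraction"))
  expect_equal(headline_fraction(prof, "cd68", percent = TRUE),
               100 * prof$fraction[prof$band == 1])
})
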
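#' Build concentric distance bands around filament bundles
#'
#' Computes the exact Euclidean distance transform from the union of all
#' filament pixels (distance in um between pixel centres via
#' `px_size_um`) and bins tissue pixels into concentric bands of width
#' `increment_um`. Band `b` holds the pixels with
#' `(b-1)*increment < d <= b*increment` (half-open on the low side);
#' pixels beyond `n_bands * increment` are labelled `-1`, filament pixels
#' `0`. With several bundles each pixel is assigned by its distance to the
#' nearest filament pixel of any bundle (a single union transform), so no
#' pixel is counted twice. Bands may be truncated by the image border.
#'
#' @param bundles a `bundle_map` from [label_bundles()], or a logical
#'   filament mask (then `px_size_um` is required).
#' @param increment_um band width in um (default 50).
#' @param n_bands number of bands (default 4, i.e. 0-200 um).
#' @param px_size_um pixel size, only needed when `bundles` is a bare
#'   mask.
#' @return An object of class `band_map`: list with `bands` (integer
#'   matrix), `increment_um`, `n_bands`, `px_size_um`.
#' @export
build_bands <- function(bundles, increment_um = 50, n_bands = 4L,
                        px_size_um = NULL) {
  stopifnot(increment_um > 0, n_bands >= 1)
  if (inherits(bundles, "bundle_map")) {
    mask <- bundles$labels > 0L
    px_size_um <- bundles$px_size_um
  } else {
    mask <- bundles
    if (is.null(px_size_um)) abort("`px_size_um` is required with a bare mask.")
  }
  if (!any(mask)) abort("bundle map / filament mask is empty.")
  d_um <- filament_distance_um(mask, px_size_um)
  bands <- ceiling(d_um / increment_um)
  bands[bands > n_bands] <- -1L
  bands[mask] <- 0L
  storage.mode(bands) <- "integer"
  structure(
    list(bands = bands, increment_um = increment_um,
         n_bands = as.integer(n_bands), px_size_um = px_size_um),
    class = "band_map"
  )
}

#' @export
print.band_map <- function(x, ...) {
  cat(sprintf("<band_map> %d band(s) of %g um (%.3g um/px)\n",
              x$n_bands, x$increment_um, x$px_size_um))
  invisible(x)
}

#' Positive-stain area fractions per band and for the whole image
#'
#' For each band `b` the fraction is
#' `|positive n band_b n tissue| / |band_b n tissue|`; the whole-image
#' fraction is `|positive n tissue| / |tissue|`. Filament pixels are never
#' part of the tissue denominator (band label 0 excludes them). Bands with
#' no tissue pixels are omitted from the table — they are missing, not
#' zero.
#'
#' @param bands a `band_map` from [build_bands()].
#' @param positive logical matrix of stain-positive pixels.
#' @param tissue logical matrix of tissue pixels.
#' @return A `band_profile`: tibble with columns `band`, `band_lo_um`,
#'   `band_hi_um`, `tissue_px`, `positive_px`, `fraction`, plus attributes
#'   `whole_fraction`, `whole_tissue_px`, `whole_positive_px` and
#'   `increment_um`. See [glance.band_profile()].
#' @export
band_fractions <- function(bands, positive, tissue) {
  stopifnot(inherits(bands, "band_map"))
  bm <- bands$bands
  if (!identical(dim(bm), dim(positive)) || !identical(dim(bm), dim(tissue))) {
    abort("`positive`, `tissue` and the band map must share dimensions.")
  }
  tissue <- tissue & bm != 0L            # filament pixels never count as tissue
  if (!any(tissue)) abort("no tissue pixels: nothing to quantify.")
  positive <- positive & tissue
  bt <- bm[tissue]
  pt <- bm[tissue & positive]
  t_cnt <- tabulate(bt[bt > 0L], nbins = bands$n_bands)
  p_cnt <- tabulate(pt[pt > 0L], nbins = bands$n_bands)
  b <- seq_len(bands$n_bands)
  out <- tibble(
    band = b,
    band_lo_um = (b - 1) * bands$increment_um,
    band_hi_um = b * bands$increment_um,
    tissue_px = t_cnt,
    positive_px = p_cnt,
    fraction = ifelse(t_cnt > 0, p_cnt / t_cnt, NA_real_)
  )
  out <- out[out$tissue_px > 0L, , drop = FALSE]
  structure(out,
            whole_fraction = sum(positive) / sum(tissue),
            whole_tissue_px = sum(tissue),
            whole_positive_px = sum(positive),
            increment_um = bands$increment_um,
            class = c("band_profile", class(out)))
}

#' One-row summary of a band profile
#' @param x a `band_profile`.
#' @param ... unused.
#' @return Tibble with `whole_fraction`, `whole_tissue_px`,
#'   `whole_positive_px`, `n_bands_reported`.
#' @export
glance.band_profile <- function(x, ...) {
  tibble(
    whole_fraction = attr(x, "whole_fraction"),
    whole_tissue_px = attr(x, "whole_tissue_px"),
    whole_positive_px = attr(x, "whole_positive_px"),
    n_bands_reported = nrow(x)
  )
}

#' Threshold the positive stain in a micrograph
#'
#' Builds the stain-positive mask for one marker chemistry:
#' * `"dab"` — colour deconvolution of the RGB optical densities with the
#'   standard published haematoxylin/DAB stain vectors, then Otsu
#'   threshold on the DAB density.
#' * `"sirius_red"` — red-dominance ratio `R / (R + G + B)` with an Otsu
#'   threshold.
#' * `"fluor"` — Otsu threshold on the fluorescence intensity.
#'
#' Thresholds are estimated over non-filament pixels only, and filament
#' pixels are always excluded from the result. A stain channel with
#' (near-)zero dynamic range yields an empty mask.
#'
#' @param img a [calibrated_image()].
#' @param marker one of `"dab"`, `"sirius_red"`, `"fluor"`; must match the
#'   image modality.
#' @param filament_mask optional logical matrix of filament pixels to
#'   exclude.
#' @param min_range minimum dynamic range of the stain signal below which
#'   the image is declared stain-free (default 0.02).
#' @return Logical matrix of positive pixels.
#' @export
positive_mask <- function(img, marker = c("dab", "sirius_red", "fluor"),
                          filament_mask = NULL, min_range = 0.02) {
  stopifnot(inherits(img, "calibrated_image"))
  marker <- match.arg(marker)
  wanted <- c(dab = "brightfield_dab", sirius_red = "brightfield_sirius",
              fluor = "fluorescence")[[marker]]
  if (img$modality != wanted) {
    abort(sprintf("marker '%s' expects a %s image, got %s.",
                  marker, wanted, img$modality))
  }
  signal <- switch(marker,
    dab = {
      od <- -log(pmax(img$pixels, 1e-4))
      flat <- matrix(od, ncol = 3L)                   # pixels x channels
      conc <- flat %*% solve(stain_vectors_hdab())    # unmix to H / DAB / res
      matrix(conc[, 2], nrow(od), ncol(od))
    },
    sirius_red = {
      px <- img$pixels
      px[, , 1] / (px[, , 1] + px[, , 2] + px[, , 3] + 1e-8)
    },
    fluor = img$pixels
  )
  candidate <- if (is.null(filament_mask)) {
    matrix(TRUE, nrow(signal), ncol(signal))
  } else {
    !filament_mask
  }
  vals <- signal[candidate]
  if (diff(range(vals)) < min_range) {
    return(matrix(FALSE, nrow(signal), ncol(signal)))
  }
  v01 <- (vals - min(vals)) / diff(range(vals))
  thr <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1)), range = c(0, 1))
  s01 <- (signal - min(vals)) / diff(range(vals))
  s01 > thr & candidate
}

#' Analysis mode for a staining marker
#'
#' Inflammatory cell markers (pan-leukocyte CD45, macrophage CD68) are
#' quantified close to the mesh filaments — the first 0-50 um band is the
#' headline statistic — because the foreign-body response concentrates at
#' the material surface. Neotissue markers (Sirius red collagen, aSMA
#' myofibroblasts, CD31 vessels) show no continuous distance gradient and
#' are quantified over the whole image.
#'
#' @param marker_kind marker name: `"cd45"`, `"cd68"`, `"sirius"`,
#'   `"asma"`, `"cd31"` (case-insensitive).
#' @return `"near_filament"` or `"whole_image"`.
#' @export
analysis_mode <- function(marker_kind) {
  key <- tolower(trimws(marker_kind))
  modes <- c(cd45 = "near_filament", cd68 = "near_filament",
             sirius = "whole_image", asma = "whole_image",
             cd31 = "whole_image")
  if (!key %in% names(modes)) {
    abort(sprintf("unknown marker '%s'; expected one of %s.",
                  marker_kind, paste(names(modes), collapse = ", ")))
  }
  unname(modes[[key]])
}

#' Headline fraction of a band profile for a marker
#'
#' Returns the band-1 (0-50 um) fraction for near-filament markers and the
#' whole-image fraction for whole-image markers, optionally as a
#' percentage.
#'
#' @param profile a `band_profile`.
#' @param marker_kind marker name understood by [analysis_mode()].
#' @param percent report as percent positive area (default `FALSE`).
#' @return A single number.
#' @export
headline_fraction <- function(profile, marker_kind, percent = FALSE) {
  mode <- analysis_mode(marker_kind)
  val <- if (mode == "near_filament") {
    if (!1L %in% profile$band) abort("band 1 is missing from the profile.")
    profile$fraction[profile$band == 1L]
  } else {
    attr(profile, "whole_fraction")
  }
  if (percent) 100 * val else val
}
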
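#' @section Filament binarization:
#' Micrograph luminance typically holds three classes: near-black mesh
#' filament cross-sections, mid-tone positive stain, and light
#' counterstained tissue (fluorescence images invert this: bright marker,
#' dim tissue, signal-void filament). A single Otsu split can land between
#' stain and tissue instead of isolating the filaments, so the filament
#' class is taken as the lowest class of a two-threshold (three-class)
#' Otsu partition of the intensity histogram.
#' @name periband-segmentation
#' @keywords internal
NULL

# exhaustive two-threshold Otsu on a 256-bin histogram of values in [0,1];
# returns the two thresholds (upper bin edges of classes 1 and 2)
multi_otsu2 <- function(values, n_bins = 256L) {
  counts <- tabulate(
    findInterval(values, seq(0, 1, length.out = n_bins + 1L),
                 rightmost.closed = TRUE, all.inside = TRUE),
    nbins = n_bins
  )
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  W <- cumsum(counts)
  S <- cumsum(counts * mids)
  tot_w <- W[n_bins]; tot_s <- S[n_bins]
  t1 <- seq_len(n_bins - 2L)
  t2 <- seq_len(n_bins - 1L)
  w1 <- W[t1]; s1 <- S[t1]
  # between-class variance term for each (t1, t2) pair, t1 < t2
  w2 <- outer(t1, t2, function(i, j) W[j] - W[i])
  s2 <- outer(t1, t2, function(i, j) S[j] - S[i])
  w3 <- tot_w - outer(t1, t2, function(i, j) W[j])
  s3 <- tot_s - outer(t1, t2, function(i, j) S[j])
  obj <- s1^2 / w1 + ifelse(w2 > 0, s2^2 / w2, 0) + ifelse(w3 > 0, s3^2 / w3, 0)
  obj[outer(t1, t2, `>=`)] <- -Inf
  obj[w1 == 0, ] <- -Inf
  best <- arrayInd(which.max(obj), dim(obj))
  c(t1[best[1]] / n_bins, t2[best[2]] / n_bins)
}

#' Binarize mesh filaments in a micrograph
#'
#' Classifies pixels as mesh filament: the darkest structures in
#' brightfield, signal-void regions in fluorescence. The threshold is the
#' lower cut of a three-class Otsu partition of luminance (fluorescence:
#' raw intensity); the candidate class is accepted only if its mean
#' intensity is at most `dark_max`, so images without filaments yield an
#' empty mask rather than spurious detections. The mask is cleaned by
#' morphological opening and hole filling.
#'
#' A blank (zero-variance) image or one with no sufficiently dark class
#' returns an all-`FALSE` mask whose `"filament_detected"` attribute is
#' `FALSE` — an explicit no-filament result, not an error.
#'
#' @param img a [calibrated_image()].
#' @param dark_max maximum mean intensity for the filament class
#'   (default 0.2).
#' @param clean_brush_px diameter (odd, px) of the disc brush used for the
#'   morphological opening; `1` disables opening.
#' @return Logical matrix marking filament pixels, with attribute
#'   `filament_detected`.
#' @export
binarize_filaments <- function(img, dark_max = 0.2, clean_brush_px = 3L) {
  stopifnot(inherits(img, "calibrated_image"))
  lum <- luminance(img$pixels)
  no_filament <- function() {
    structure(matrix(FALSE, nrow(lum), ncol(lum)), filament_detected = FALSE)
  }
  if (diff(range(lum)) < 1e-6) return(no_filament())
  thr <- multi_otsu2(lum)
  mask <- lum <= thr[1]
  if (!any(mask) || mean(lum[mask]) > dark_max) return(no_filament())
  if (clean_brush_px > 1L) {
    brush <- EBImage::makeBrush(as.integer(clean_brush_px), shape = "disc")
    mask <- EBImage::imageData(
      EBImage::opening(EBImage::Image(mask), brush)) > 0.5
  }
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0.5
  structure(mask, filament_detected = TRUE)
}

# deterministic 8-connected component labelling via igraph; returns an
# integer matrix (0 = background), components numbered by their first
# pixel in column-major order
label_components_8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  n_fg <- sum(mask)
  if (n_fg == 0L) return(labels)
  id <- matrix(0L, h, w)
  id[mask] <- seq_len(n_fg)
  pair <- function(a, b) {
    keep <- a > 0L & b > 0L
    cbind(a[keep], b[keep])
  }
  edges <- rbind(
    pair(id[-h, , drop = FALSE], id[-1, , drop = FALSE]),   # down
    pair(id[, -w, drop = FALSE], id[, -1, drop = FALSE]),   # right
    pair(id[-h, -w, drop = FALSE], id[-1, -1, drop = FALSE]), # down-right
    pair(id[-h, -1, drop = FALSE], id[-1, -w, drop = FALSE])  # down-left
  )
  g <- igraph::make_empty_graph(n = n_fg, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # renumber components by first occurrence (column-major pixel order)
  first <- match(unique(memb), memb)
  relab <- integer(max(memb))
  relab[memb[sort(first)]] <- seq_along(first)
  labels[mask] <- relab[memb]
  labels
}

#' Label filament bundles
#'
#' Groups filament pixels into bundles: monofilaments of one knitted yarn
#' lie closer together than filaments of different yarns, so the mask is
#' morphologically closed with a disc of radius `merge_radius_um` before
#' 8-connected component labelling — components whose gap is below about
#' twice that radius merge into one bundle. Components smaller than
#' `min_area_um2` (in original filament pixels) are discarded. Labels in
#' the returned raster mark only original filament pixels.
#'
#' @param filament_mask logical matrix from [binarize_filaments()].
#' @param px_size_um pixel size in um.
#' @param merge_radius_um closing radius in um (default 30).
#' @param min_area_um2 minimum bundle area in um^2 (default 1000).
#' @return An object of class `bundle_map`: list with `labels` (integer
#'   matrix, 0 = non-filament), `px_size_um`, and `props`, a tibble with
#'   one row per bundle (`bundle`, `n_px`, `area_um2`, `centroid_row_px`,
#'   `centroid_col_px`).
#' @export
label_bundles <- function(filament_mask, px_size_um,
                          merge_radius_um = 30, min_area_um2 = 1000) {
  if (!any(filament_mask)) abort("filament mask is empty; nothing to label.")
  stopifnot(px_size_um > 0, merge_radius_um >= 0, min_area_um2 >= 0)
  r_px <- round(merge_radius_um / px_size_um)
  closed <- filament_mask
  if (r_px >= 1) {
    brush <- EBImage::makeBrush(as.integer(2 * r_px + 1), shape = "disc")
    closed <- EBImage::imageData(
      EBImage::closing(EBImage::Image(filament_mask), brush)) > 0.5
  }
  comp <- label_components_8(closed)
  labels <- matrix(0L, nrow(filament_mask), ncol(filament_mask))
  labels[filament_mask] <- comp[filament_mask]
  props <- bundle_props(labels, px_size_um)
  keep <- props$area_um2 >= min_area_um2
  if (!any(keep)) abort("no bundle reaches `min_area_um2`.")
  drop_ids <- props$bundle[!keep]
  labels[labels %in% drop_ids] <- 0L
  # compact label ids so bundles are numbered 1..K
  old <- props$bundle[keep]
  relab <- integer(max(old))
  relab[old] <- seq_along(old)
  labels[labels > 0L] <- relab[labels[labels > 0L]]
  structure(
    list(labels = labels, px_size_um = px_size_um,
         props = bundle_props(labels, px_size_um)),
    class = "bundle_map"
  )
}

bundle_props <- function(labels, px_size_um) {
  ids <- sort(unique(labels[labels > 0L]))
  rows <- purrr::map(ids, function(b) {
    idx <- which(labels == b, arr.ind = TRUE)
    tibble(
      bundle = b,
      n_px = nrow(idx),
      area_um2 = nrow(idx) * px_size_um^2,
      centroid_row_px = mean(idx[, 1]),
      centroid_col_px = mean(idx[, 2])
    )
  })
  if (length(rows) == 0L) {
    return(tibble(bundle = integer(), n_px = integer(), area_um2 = double(),
                  centroid_row_px = double(), centroid_col_px = double()))
  }
  bind_rows(rows)
}

#' @export
print.bundle_map <- function(x, ...) {
  cat(sprintf("<bundle_map> %d bundle(s), %.3g um/px\n",
              nrow(x$props), x$px_size_um))
  print(x$props)
  invisible(x)
}

#' Tidy a bundle map into its per-bundle property table
#' @param x a `bundle_map`.
#' @param ... unused.
#' @return A tibble with one row per bundle.
#' @export
tidy.bundle_map <- function(x, ...) x$props

#' Keep the bundles closest to the image centre
#'
#' Micrograph fields are framed on the most central filament bundles to
#' avoid edge effects and suture sites; this selects the `k` bundles whose
#' centroids lie nearest the image centre (Euclidean distance in pixels),
#' breaking ties by lower bundle id. With fewer than `k` bundles all are
#' kept and a warning is raised. Selection keeps original bundle ids, so
#' applying it twice with the same `k` is a no-op.
#'
#' @param bundles a `bundle_map`.
#' @param k number of bundles to keep (default 4).
#' @return A `bundle_map` containing only the selected bundles.
#' @export
select_central_bundles <- function(bundles, k = 4L) {
  stopifnot(inherits(bundles, "bundle_map"))
  if (k < 1L) abort("`k` must be >= 1.")
  props <- bundles$props
  if (nrow(props) == 0L) abort("bundle map holds no bundles.")
  ctr <- (dim(bundles$labels) + 1) / 2
  d <- sqrt((props$centroid_row_px - ctr[1])^2 +
            (props$centroid_col_px - ctr[2])^2)
  ord <- order(d, props$bundle)
  if (nrow(props) < k) {
    warn(sprintf("only %d bundle(s) available; keeping all (k = %d).",
                 nrow(props), k))
  }
  keep <- sort(props$bundle[ord[seq_len(min(k, nrow(props)))]])
  labels <- bundles$labels
  labels[!(labels %in% keep)] <- 0L
  structure(
    list(labels = labels, px_size_um = bundles$px_size_um,
         props = props[props$bundle %in% keep, , drop = FALSE]),
    class = "bundle_map"
  )
}
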
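#' Define a synthetic histology scene
#'
#' Describes a micrograph of mesh filament bundles embedded in stained
#' tissue. Filament monofilaments appear as circular cross-sections
#' (~100 um diameter in knitted yarns) grouped in bundles; each tissue
#' pixel is stain-positive with probability
#' `p(d) = floor + (p0 - floor) * exp(-d / lambda_um)`, where `d` is the
#' Euclidean distance (um) from the nearest filament pixel. A finite
#' `lambda_um` emulates the inflammatory gradient of leukocyte/macrophage
#' markers concentrated at the material surface; `lambda_um = Inf` gives a
#' distance-independent stain (collagen, vessel or myofibroblast markers).
#'
#' @param width_px,height_px image size in pixels (>= 64).
#' @param px_size_um pixel size in um (> 0).
#' @param filaments tibble of filament circles with columns `bundle`
#'   (integer id), `cx_um`, `cy_um` (centre, um from the top-left corner)
#'   and `r_um` (radius, um). Circles of one bundle may touch; circles of
#'   different bundles must not overlap.
#' @param stain_mode `"brightfield_dab"`, `"brightfield_sirius"` or
#'   `"fluorescence"`.
#' @param p0 positive probability at the filament surface, in `[0, 1]`.
#' @param lambda_um decay length of the gradient in um (> 0, or `Inf` for
#'   a flat profile; with `Inf` every tissue pixel is positive with
#'   probability `p0`).
#' @param floor distant baseline positive probability, `<= p0`.
#' @param noise_sd Gaussian intensity noise SD added to the rendered image
#'   (clipped to `[0, 1]`).
#' @param margin_px width of a background (non-tissue) border; default 0
#'   so the whole image is tissue plus filament.
#' @return An object of class `histology_scene`.
#' @export
histology_scene <- function(width_px = 256L,
                            height_px = 256L,
                            px_size_um = 2,
                            filaments,
                            stain_mode = c("brightfield_dab",
                                           "brightfield_sirius",
                                           "fluorescence"),
                            p0 = 0.8,
                            lambda_um = 50,
                            floor = 0.05,
                            noise_sd = 0,
                            margin_px = 0L) {
  stain_mode <- match.arg(stain_mode)
  stopifnot(width_px >= 64, height_px >= 64, px_size_um > 0, noise_sd >= 0,
            margin_px >= 0)
  if (p0 < 0 || p0 > 1 || floor < 0 || floor > 1) {
    abort("`p0` and `floor` must lie in [0, 1].")
  }
  if (p0 < floor) abort("`p0` must be >= `floor`.")
  if (!(lambda_um > 0)) abort("`lambda_um` must be > 0 (or Inf).")
  filaments <- as_tibble(filaments)
  need <- c("bundle", "cx_um", "cy_um", "r_um")
  if (!all(need %in% names(filaments)) || nrow(filaments) < 1L) {
    abort("`filaments` needs >= 1 row with columns bundle, cx_um, cy_um, r_um.")
  }
  w_um <- width_px * px_size_um
  h_um <- height_px * px_size_um
  inside <- filaments$cx_um - filaments$r_um >= 0 &
    filaments$cx_um + filaments$r_um <= w_um &
    filaments$cy_um - filaments$r_um >= 0 &
    filaments$cy_um + filaments$r_um <= h_um
  if (!all(inside)) abort("all filament circles must lie inside the image.")
  # circles of different bundles must not overlap
  if (length(unique(filaments$bundle)) > 1L) {
    idx <- utils::combn(nrow(filaments), 2L)
    for (j in seq_len(ncol(idx))) {
      a <- idx[1, j]; b <- idx[2, j]
      if (filaments$bundle[a] == filaments$bundle[b]) next
      gap <- sqrt((filaments$cx_um[a] - filaments$cx_um[b])^2 +
                  (filaments$cy_um[a] - filaments$cy_um[b])^2) -
        filaments$r_um[a] - filaments$r_um[b]
      if (gap <= 0) abort("bundles overlap: circles of different bundles touch.")
    }
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         px_size_um = px_size_um, filaments = filaments,
         stain_mode = stain_mode, p0 = p0, lambda_um = lambda_um,
         floor = floor, noise_sd = noise_sd, margin_px = as.integer(margin_px)),
    class = "histology_scene"
  )
}

#' Lay out filament bundles for a scene
#'
#' Convenience constructor for the `filaments` table of
#' [histology_scene()]. Each bundle is a ring of touching monofilament
#' circles (a knitted-yarn cross-section); a single-filament bundle is one
#' circle. Bundle centres are either supplied or placed on a jittered grid
#' so that bundles never overlap.
#'
#' @param n_bundles number of bundles (1-4 is typical).
#' @param filaments_per_bundle circles per bundle (1-6).
#' @param r_um monofilament radius in um (default 50, i.e. 100 um
#'   diameter).
#' @param width_um,height_um scene extent in um.
#' @param centers optional 2-column matrix/data frame of bundle centres
#'   (um); if omitted, centres are placed deterministically on a grid.
#' @return A tibble with columns `bundle`, `cx_um`, `cy_um`, `r_um`.
#' @export
bundle_layout <- function(n_bundles = 1L,
                          filaments_per_bundle = 3L,
                          r_um = 50,
                          width_um = 512,
                          height_um = 512,
                          centers = NULL) {
  stopifnot(n_bundles >= 1, filaments_per_bundle >= 1,
            filaments_per_bundle <= 6, r_um > 0)
  k <- filaments_per_bundle
  ring <- if (k == 1L) 0 else r_um / sin(pi / k) # touching circles on a ring
  bundle_r <- ring + r_um
  if (is.null(centers)) {
    ncol_g <- ceiling(sqrt(n_bundles))
    nrow_g <- ceiling(n_bundles / ncol_g)
    gx <- width_um * (seq_len(ncol_g) - 0.5) / ncol_g
    gy <- height_um * (seq_len(nrow_g) - 0.5) / nrow_g
    centers <- expand.grid(cx = gx, cy = gy)[seq_len(n_bundles), ]
  } else {
    centers <- as.data.frame(centers)
    names(centers) <- c("cx", "cy")
    stopifnot(nrow(centers) == n_bundles)
  }
  out <- purrr::map(seq_len(n_bundles), function(b) {
    ang <- if (k == 1L) 0 else 2 * pi * (seq_len(k) - 1) / k + pi / 4
    tibble(
      bundle = b,
      cx_um = centers$cx[b] + ring * cos(ang),
      cy_um = centers$cy[b] + ring * sin(ang),
      r_um = r_um
    )
  })
  out <- bind_rows(out)
  if (any(out$cx_um - r_um < 0 | out$cx_um + r_um > width_um |
          out$cy_um - r_um < 0 | out$cy_um + r_um > height_um)) {
    abort("bundle layout does not fit inside the scene; enlarge the scene or shrink r_um.")
  }
  out
}

# rasterize filament circles; pixel centres at ((col-0.5)*px, (row-0.5)*px) um
rasterize_filaments <- function(scene) {
  h <- scene$height_px; w <- scene$width_px; px <- scene$px_size_um
  xc <- (seq_len(w) - 0.5) * px
  yc <- (seq_len(h) - 0.5) * px
  mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(scene$filaments))) {
    f <- scene$filaments[i, ]
    dx2 <- (xc - f$cx_um)^2
    dy2 <- (yc - f$cy_um)^2
    mask <- mask | outer(dy2, dx2, `+`) <= f$r_um^2
  }
  mask
}

# exact Euclidean distance (um) from each pixel centre to the nearest
# filament pixel centre; 0 on filament pixels
filament_distance_um <- function(filament_mask, px_size_um) {
  if (!any(filament_mask)) abort("filament mask is empty.")
  d <- EBImage::distmap(EBImage::Image(1 - filament_mask), metric = "euclidean")
  EBImage::imageData(d) * px_size_um
}

# expected positive probability at distance d (um)
decay_probability <- function(d_um, p0, floor, lambda_um) {
  floor + (p0 - floor) * exp(-d_um / lambda_um)
}

# Ruifrok-Johnston normalized optical-density vectors for haematoxylin and
# DAB; third channel is their residual (cross product)
stain_vectors_hdab <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  h <- h / sqrt(sum(h^2)); d <- d / sqrt(sum(d^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  rbind(h, d, r / sqrt(sum(r^2)))
}

# render one channel stack from masks; Beer-Lambert for brightfield
render_scene <- function(scene, filament, tissue, positive) {
  h <- scene$height_px; w <- scene$width_px
  if (scene$stain_mode == "fluorescence") {
    img <- matrix(0.02, h, w)          # background near-black
    img[tissue] <- 0.25                # dim autofluorescence
    img[positive] <- 0.90              # marker signal
    img[filament] <- 0.0               # signal void
    return(img)
  }
  px <- array(1, dim = c(h, w, 3))     # white background
  if (scene$stain_mode == "brightfield_dab") {
    v <- stain_vectors_hdab()
    od_t <- 0.55 * v[1, ]              # haematoxylin counterstain
    od_p <- od_t + 1.0 * v[2, ]        # + DAB chromogen
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[tissue] <- exp(-od_t[ch])
      plane[positive] <- exp(-od_p[ch])
      plane[filament] <- 0.05
      px[, , ch] <- plane
    }
  } else {                             # brightfield_sirius
    col_t <- c(0.88, 0.82, 0.78)       # pale tissue
    col_p <- c(0.72, 0.12, 0.15)       # Sirius red collagen
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[tissue] <- col_t[ch]
      plane[positive] <- col_p[ch]
      plane[filament] <- 0.05
      px[, , ch] <- plane
    }
  }
  px
}

#' Generate a synthetic micrograph with ground-truth masks
#'
#' Renders the scene into a [calibrated_image()] and returns the
#' ground-truth filament, tissue and positive masks along with the exact
#' distance map used to draw the stain. Filaments render as the darkest
#' (brightfield) or signal-void (fluorescence) structures. The truth masks
#' satisfy `positive` ⊆ `tissue` and `tissue` ∩ `filament` = ∅.
#'
#' @param scene a [histology_scene()].
#' @param seed integer seed; identical seeds give identical output.
#' @return A list of class `histology_sim` with elements `image`
#'   ([calibrated_image()]), `truth` (list of logical matrices `filament`,
#'   `tissue`, `positive`), `distance_um` (numeric matrix) and `scene`.
#' @export
generate_histology <- function(scene, seed = NULL) {
  stopifnot(inherits(scene, "histology_scene"))
  gen <- function() {
    filament <- rasterize_filaments(scene)
    tissue <- !filament
    if (scene$margin_px > 0L) {
      m <- scene$margin_px
      border <- matrix(TRUE, scene$height_px, scene$width_px)
      border[(m + 1):(scene$height_px - m), (m + 1):(scene$width_px - m)] <- FALSE
      tissue <- tissue & !border
    }
    d_um <- filament_distance_um(filament, scene$px_size_um)
    p <- decay_probability(d_um, scene$p0, scene$floor, scene$lambda_um)
    positive <- tissue & matrix(runif(length(p)) < p,
                                scene$height_px, scene$width_px)
    px <- render_scene(scene, filament, tissue, positive)
    if (scene$noise_sd > 0) {
      px <- px + rnorm(length(px), sd = scene$noise_sd)
      px <- pmin(pmax(px, 0), 1)
    }
    structure(
      list(
        image = calibrated_image(px, scene$px_size_um, scene$stain_mode),
        truth = list(filament = filament, tissue = tissue, positive = positive),
        distance_um = d_um,
        scene = scene
      ),
      class = "histology_sim"
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Write a histology simulation to disk
#'
#' Writes the rendered image as TIFF, the three truth masks as PNG, and a
#' JSON sidecar with the scene parameters.
#'
#' @param sim a `histology_sim` from [generate_histology()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return The named vector of paths written, invisibly.
#' @export
write_histology_sim <- function(sim, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image = file.path(dir, paste0(stem, ".tiff")),
    filament = file.path(dir, paste0(stem, "_filament.png")),
    tissue = file.path(dir, paste0(stem, "_tissue.png")),
    positive = file.path(dir, paste0(stem, "_positive.png")),
    scene = file.path(dir, paste0(stem, "_scene.json"))
  )
  write_calibrated_image(sim$image, paths[["image"]])
  png::writePNG(sim$truth$filament * 1, paths[["filament"]])
  png::writePNG(sim$truth$tissue * 1, paths[["tissue"]])
  png::writePNG(sim$truth$positive * 1, paths[["positive"]])
  sc <- sim$scene
  sc$filaments <- as.data.frame(sc$filaments)
  jsonlite::write_json(unclass(sc), paths[["scene"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
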
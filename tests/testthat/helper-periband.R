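# Brute-force oracles used across the suite. These deliberately share no
# code with the package internals: per-pixel enumeration instead of a
# distance transform, recursive flood fill instead of graph components,
# explicit rank arithmetic instead of kruskal.test.

# per-pixel Euclidean distance (um) from every pixel centre to the
# nearest TRUE pixel centre of `mask`
bf_distance_um <- function(mask, px_size_um) {
  fg <- which(mask, arr.ind = TRUE)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      out[r, cc] <- sqrt(min((fg[, 1] - r)^2 + (fg[, 2] - cc)^2))
    }
  }
  out * px_size_um
}

# band labels by per-pixel nearest-filament search: 0 filament, 1..n
# bands with (b-1)*inc < d <= b*inc, -1 beyond
bf_band_labels <- function(mask, px_size_um, increment_um, n_bands) {
  d <- bf_distance_um(mask, px_size_um)
  b <- ceiling(d / increment_um)
  b[b > n_bands] <- -1L
  b[mask] <- 0L
  storage.mode(b) <- "integer"
  b
}

# 8-connected components by iterative flood fill (stack-based)
bf_components_8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    while (length(stack) > 0L) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[i] != 0L) next
      lab[i] <- nxt
      r <- (i - 1L) %% h + 1L
      cc <- (i - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        if (rr >= 1L && rr <= h && ccc >= 1L && ccc <= w) {
          j <- (ccc - 1L) * h + rr
          if (mask[j] && lab[j] == 0L) stack <- c(stack, j)
        }
      }
    }
  }
  lab
}

# tie-corrected Kruskal-Wallis H from explicit rank sums
bf_kruskal_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  groups <- factor(groups)
  Ri <- tapply(r, groups, sum)
  ni <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# two filaments 10 um apart in one "bundle", plus a far second bundle;
# circles do not touch, so no interstice is enclosed by hole filling
two_circle_filaments <- function() {
  tibble::tibble(
    bundle = c(1L, 1L, 2L),
    cx_um = c(150, 260, 380),
    cy_um = c(150, 150, 380),
    r_um = 50
  )
}

default_test_scene <- function(noise_sd = 0, stain_mode = "brightfield_dab",
                               p0 = 0.8, lambda_um = 50, floor = 0.05,
                               n_px = 256L, px = 2) {
  histology_scene(
    width_px = n_px, height_px = n_px, px_size_um = px,
    filaments = bundle_layout(1, 3, width_um = n_px * px,
                              height_um = n_px * px),
    stain_mode = stain_mode, p0 = p0, lambda_um = lambda_um,
    floor = floor, noise_sd = noise_sd
  )
}

# strip class/attributes for matrix comparison
as_plain <- function(m) matrix(m, nrow(m), ncol(m))

new_curve_for_test <- function(x, y) {
  periband:::new_tensile_curve(tibble::tibble(elongation_mm = x, load_N = y))
}
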
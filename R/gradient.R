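#' Test for a diminishing peri-filament staining gradient
#'
#' Given per-animal positive-area fractions in concentric distance bands,
#' runs a Kruskal-Wallis omnibus test across band indices, all pairwise
#' two-sided rank-sum comparisons between bands with Bonferroni
#' correction, and a monotone-trend summary (Spearman rank correlation of
#' band index vs fraction). A *diminishing gradient* — staining
#' concentrated at the filament surface and falling off with distance, the
#' signature of the foreign-body reaction — is declared when the omnibus
#' p-value is below `alpha` and the trend is negative.
#'
#' @param profiles tibble with columns `animal`, `band` (integer) and
#'   `fraction` (one value per animal and band, e.g. the mean over that
#'   animal's analysed fields). Missing fractions are dropped.
#' @param alpha significance level (default 0.05).
#' @return An object of class `gradient_result`.
#' @export
gradient_test <- function(profiles, alpha = 0.05) {
  profiles <- as_tibble(profiles)
  need <- c("animal", "band", "fraction")
  if (!all(need %in% names(profiles))) {
    abort("`profiles` needs columns animal, band, fraction.")
  }
  profiles <- profiles[!is.na(profiles$fraction), , drop = FALSE]
  bands <- sort(unique(profiles$band))
  if (length(bands) < 2L) abort("need at least 2 non-missing bands.")
  if (length(unique(profiles$animal)) < 3L) abort("need at least 3 animals.")
  if (stats::var(profiles$fraction) == 0) {
    # all fractions identical: no evidence of any gradient
    omnibus <- tibble(statistic = 0, df = length(bands) - 1L, p_value = 1)
    rho <- 0
  } else {
    kw <- kruskal.test(profiles$fraction, factor(profiles$band))
    omnibus <- tibble(statistic = unname(kw$statistic),
                      df = unname(kw$parameter),
                      p_value = kw$p.value)
    rho <- suppressWarnings(
      cor(profiles$band, profiles$fraction, method = "spearman"))
  }
  pairs <- utils::combn(bands, 2L)
  m <- ncol(pairs)
  raw <- vapply(seq_len(m), function(j) {
    a <- profiles$fraction[profiles$band == pairs[1, j]]
    b <- profiles$fraction[profiles$band == pairs[2, j]]
    if (length(unique(c(a, b))) == 1L) return(1)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  pairwise <- tibble(
    band_a = pairs[1, ], band_b = pairs[2, ],
    p_raw = raw,
    p_adj = p.adjust(raw, method = "bonferroni")
  )
  structure(
    list(omnibus = omnibus, pairwise = pairwise, rho = rho, alpha = alpha,
         gradient = omnibus$p_value < alpha && rho < 0,
         n_animals = length(unique(profiles$animal)),
         n_bands = length(bands)),
    class = "gradient_result"
  )
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf(
    "<gradient_result> Kruskal-Wallis H = %.3f (df = %d), p = %.3g; Spearman rho = %.2f\n%s\n",
    x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value, x$rho,
    if (x$gradient) "Diminishing gradient declared." else "No diminishing gradient."
  ))
  invisible(x)
}

#' Pairwise band comparisons of a gradient test
#' @param x a `gradient_result`.
#' @param ... unused.
#' @return Tibble of band pairs with raw and Bonferroni-adjusted p-values.
#' @export
tidy.gradient_result <- function(x, ...) x$pairwise

#' One-row summary of a gradient test
#' @param x a `gradient_result`.
#' @param ... unused.
#' @return Tibble with the omnibus statistic, p-value, trend and verdict.
#' @export
glance.gradient_result <- function(x, ...) {
  tibble(
    statistic = x$omnibus$statistic, df = x$omnibus$df,
    p_value = x$omnibus$p_value, rho = x$rho,
    gradient = x$gradient, n_animals = x$n_animals, n_bands = x$n_bands
  )
}

#' Simulate per-animal band profiles from a histology scene
#'
#' Draws `images_per_animal` synthetic fields per animal from one scene
#' and returns each animal's mean band fractions — the unit that enters
#' [gradient_test()]. The scene geometry (and hence the distance
#' transform and band map) is computed once and shared across fields;
#' every field redraws the per-pixel Bernoulli stain, which is exactly
#' what [generate_histology()] does image by image.
#'
#' @param scene a [histology_scene()].
#' @param n_animals number of animals (default 6).
#' @param images_per_animal fields averaged per animal (default 4).
#' @param increment_um,n_bands band geometry as in [build_bands()].
#' @param seed integer seed.
#' @return Tibble with columns `animal`, `band`, `fraction`.
#' @export
simulate_gradient_profiles <- function(scene,
                                       n_animals = 6L,
                                       images_per_animal = 4L,
                                       increment_um = 50,
                                       n_bands = 4L,
                                       seed = NULL) {
  stopifnot(inherits(scene, "histology_scene"),
            n_animals >= 1, images_per_animal >= 1)
  filament <- rasterize_filaments(scene)
  d_um <- filament_distance_um(filament, scene$px_size_um)
  p <- decay_probability(d_um, scene$p0, scene$floor, scene$lambda_um)
  bands <- build_bands(filament, increment_um = increment_um,
                       n_bands = n_bands, px_size_um = scene$px_size_um)
  tissue <- !filament
  idx <- which(tissue & bands$bands > 0L)
  band_of <- bands$bands[idx]
  t_cnt <- tabulate(band_of, nbins = n_bands)
  p_idx <- p[idx]
  npx <- length(p)
  draw_fractions <- function() {
    # same Bernoulli stream layout as generate_histology: one uniform per pixel
    pos <- runif(npx)[idx] < p_idx
    tabulate(band_of[pos], nbins = n_bands) / t_cnt
  }
  gen <- function() {
    rows <- purrr::map(seq_len(n_animals), function(a) {
      fr <- rowMeans(vapply(seq_len(images_per_animal),
                            function(i) draw_fractions(),
                            numeric(n_bands)))
      tibble(animal = a, band = seq_len(n_bands), fraction = fr)
    })
    bind_rows(rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
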
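#' Ground truth for a synthetic load-elongation curve
#'
#' Describes a bilinear tensile response: a compliant toe region up to
#' `breakpoint_mm`, then a stiffer linear region — the shape explanted
#' meshes show after tissue ingrowth. Load noise is additive Gaussian.
#'
#' @param toe_slope toe-region stiffness in N/mm (>= 0).
#' @param linear_slope linear-region stiffness in N/mm
#'   (`>= toe_slope`).
#' @param breakpoint_mm elongation at the regime change (> 0).
#' @param gauge_mm initial specimen length between grips (default 14).
#' @param noise_sd_N SD of additive load noise in N (>= 0).
#' @return An object of class `tensile_truth`.
#' @export
tensile_truth <- function(toe_slope,
                          linear_slope,
                          breakpoint_mm,
                          gauge_mm = 14,
                          noise_sd_N = 0) {
  if (!(toe_slope >= 0)) abort("`toe_slope` must be >= 0.")
  if (linear_slope < toe_slope) abort("`linear_slope` must be >= `toe_slope`.")
  if (!(breakpoint_mm > 0)) abort("`breakpoint_mm` must be > 0.")
  stopifnot(gauge_mm > 0, noise_sd_N >= 0)
  structure(
    list(toe_slope = toe_slope, linear_slope = linear_slope,
         breakpoint_mm = breakpoint_mm, gauge_mm = gauge_mm,
         noise_sd_N = noise_sd_N),
    class = "tensile_truth"
  )
}

# noiseless bilinear load at elongation x
bilinear_load <- function(x, toe_slope, linear_slope, breakpoint_mm) {
  ifelse(x <= breakpoint_mm,
         toe_slope * x,
         toe_slope * breakpoint_mm + linear_slope * (x - breakpoint_mm))
}

#' Generate a synthetic load-elongation curve
#'
#' Samples the bilinear truth on an evenly spaced elongation grid and adds
#' Gaussian load noise. Elongation is strictly increasing; a fixed seed
#' reproduces the curve exactly.
#'
#' @param truth a [tensile_truth()].
#' @param n_points number of samples (>= 4).
#' @param max_elongation_mm largest elongation (must exceed the
#'   breakpoint).
#' @param seed integer seed for the load noise.
#' @return A `tensile_curve`: a tibble with columns `elongation_mm`,
#'   `load_N` and attributes `gauge_mm`, `preload_N` (`NA` until trimmed)
#'   and `trimmed = FALSE`.
#' @export
generate_tensile <- function(truth, n_points = 100L, max_elongation_mm,
                             seed = NULL) {
  stopifnot(inherits(truth, "tensile_truth"))
  if (n_points < 4L) abort("`n_points` must be >= 4.")
  if (!(max_elongation_mm > truth$breakpoint_mm)) {
    abort("`max_elongation_mm` must exceed the breakpoint.")
  }
  x <- seq(0, max_elongation_mm, length.out = n_points)
  gen <- function() {
    y <- bilinear_load(x, truth$toe_slope, truth$linear_slope,
                       truth$breakpoint_mm)
    if (truth$noise_sd_N > 0) y <- y + rnorm(n_points, sd = truth$noise_sd_N)
    new_tensile_curve(tibble(elongation_mm = x, load_N = y),
                      gauge_mm = truth$gauge_mm)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

new_tensile_curve <- function(df, gauge_mm = 14, preload_N = NA_real_,
                              trimmed = FALSE) {
  df <- as_tibble(df)
  stopifnot(all(c("elongation_mm", "load_N") %in% names(df)))
  if (is.unsorted(df$elongation_mm)) {
    abort("elongation must be non-decreasing.")
  }
  if (!all(is.finite(df$load_N))) abort("loads must be finite.")
  structure(df,
            gauge_mm = gauge_mm, preload_N = preload_N, trimmed = trimmed,
            class = c("tensile_curve", class(df)))
}

#' Gauge length of a tensile curve
#' @param curve a `tensile_curve`.
#' @return gauge length in mm.
#' @export
gauge_length <- function(curve) attr(curve, "gauge_mm") %||% 14
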
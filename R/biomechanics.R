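#' Tensile strain as a percentage of gauge length
#'
#' Strain (%) is elongation divided by the initial specimen length
#' (gauge length) times 100. Values are rounded to `signif` significant
#' figures for reporting (the convention used for explant mechanics);
#' pass `signif = NULL` for the exact value.
#'
#' @param elongation_mm elongation(s) in mm (>= 0).
#' @param gauge_mm gauge length in mm (default 14, the standard explant
#'   grip separation).
#' @param signif significant figures for reporting (default 2), or `NULL`.
#' @return Strain in percent, vectorized over `elongation_mm`.
#' @export
strain_percent <- function(elongation_mm, gauge_mm = 14, signif = 2) {
  if (!(gauge_mm > 0)) abort("`gauge_mm` must be > 0.")
  if (any(elongation_mm < 0)) abort("elongation must be >= 0.")
  s <- 100 * elongation_mm / gauge_mm
  if (is.null(signif)) s else base::signif(s, signif)
}

#' Trim a load-elongation curve at the pre-load
#'
#' Specimens are pre-loaded (default 100 mN) to remove slack before
#' testing; analysis starts where the load first reaches the pre-load.
#' Samples before the crossing are dropped, the crossing point itself is
#' found by linear interpolation and becomes the new elongation origin
#' (first sample `(0, preload_N)`). Trimming an already-trimmed curve is a
#' no-op.
#'
#' @param curve a `tensile_curve` (or tibble with `elongation_mm`,
#'   `load_N`).
#' @param preload_N pre-load in N (default 0.1, i.e. 100 mN).
#' @return A trimmed `tensile_curve` (attribute `trimmed = TRUE`).
#' @export
trim_preload <- function(curve, preload_N = 0.1) {
  if (isTRUE(attr(curve, "trimmed"))) return(curve)
  x <- curve$elongation_mm
  y <- curve$load_N
  if (max(y) < preload_N) abort("curve never reaches the pre-load.")
  i <- which(y >= preload_N)[1]
  if (i == 1L) {
    out <- tibble(elongation_mm = x - x[1], load_N = y)
  } else {
    # linear interpolation of the crossing elongation
    x0 <- x[i - 1] + (preload_N - y[i - 1]) * (x[i] - x[i - 1]) / (y[i] - y[i - 1])
    out <- tibble(
      elongation_mm = c(0, x[i:length(x)] - x0),
      load_N = c(preload_N, y[i:length(y)])
    )
  }
  new_tensile_curve(out, gauge_mm = gauge_length(curve),
                    preload_N = preload_N, trimmed = TRUE)
}

#' Drop the failure region of a curve
#'
#' Samples after the peak load (specimen failure) are discarded before
#' averaging or stiffness fitting.
#'
#' @param curve a `tensile_curve`.
#' @return The curve up to and including its peak load.
#' @export
trim_failure <- function(curve) {
  peak <- which.max(curve$load_N)
  out <- curve[seq_len(peak), , drop = FALSE]
  new_tensile_curve(tibble(elongation_mm = out$elongation_mm,
                           load_N = out$load_N),
                    gauge_mm = gauge_length(curve),
                    preload_N = attr(curve, "preload_N") %||% NA_real_,
                    trimmed = isTRUE(attr(curve, "trimmed")))
}

#' Average several load-elongation curves with a 95% confidence envelope
#'
#' Each curve is linearly interpolated onto a common elongation grid; the
#' mean load and a pointwise Student-t confidence interval (n - 1 df) are
#' computed per grid point.
#'
#' @param curves list of `tensile_curve`s (>= 2), already pre-load-trimmed
#'   and failure-trimmed as appropriate.
#' @param grid elongation grid (mm); default 50 points across the common
#'   support of all curves.
#' @param conf confidence level (default 0.95).
#' @return Tibble with `elongation_mm`, `mean_load_N`, `ci_lo`, `ci_hi`,
#'   `n`, of class `average_curve`.
#' @export
average_curve <- function(curves, grid = NULL, conf = 0.95) {
  if (length(curves) < 2L) abort("need at least 2 curves.")
  lo <- max(vapply(curves, function(cv) min(cv$elongation_mm), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$elongation_mm), numeric(1)))
  if (is.null(grid)) grid <- seq(lo, hi, length.out = 50L)
  if (min(grid) < lo - 1e-9 || max(grid) > hi + 1e-9) {
    abort("grid extends outside the common elongation support.")
  }
  mat <- vapply(curves, function(cv) {
    approx(cv$elongation_mm, cv$load_N, xout = grid, ties = "ordered")$y
  }, numeric(length(grid)))
  n <- length(curves)
  m <- rowMeans(mat)
  se <- apply(mat, 1, sd) / sqrt(n)
  tcrit <- qt(1 - (1 - conf) / 2, df = n - 1)
  structure(
    tibble(elongation_mm = grid, mean_load_N = m,
           ci_lo = m - tcrit * se, ci_hi = m + tcrit * se, n = n),
    conf = conf,
    class = c("average_curve", class(tibble())))
}

#' Segmented (toe/linear) stiffness fit of a load-elongation curve
#'
#' Explanted meshes show a bilinear response: a compliant toe region
#' followed by a stiffer linear region. This fits two connected line
#' segments by least squares: for every candidate breakpoint on the
#' sample grid the model `load ~ elongation + max(elongation - c, 0)` is
#' fitted and the breakpoint minimising the residual sum of squares is
#' kept; with `refine = TRUE` the breakpoint is then polished by a
#' continuous 1-D optimisation between its grid neighbours. Mesh
#' stiffness is the slope of the curve — `linear_slope` is the headline
#' stiffness.
#'
#' When the two slopes differ by less than `distinct_tol` (relative),
#' the curve is effectively one straight line and `distinct_toe` is
#' `FALSE`.
#'
#' @param curve a `tensile_curve` with at least 6 samples.
#' @param refine polish the breakpoint continuously (default `TRUE`).
#' @param distinct_tol relative slope difference below which no distinct
#'   toe region is declared (default 0.05).
#' @return An object of class `bilinear_fit` with `toe_slope`,
#'   `linear_slope` (N/mm), `breakpoint_mm`, `rss`, `distinct_toe`.
#' @export
fit_bilinear <- function(curve, refine = TRUE, distinct_tol = 0.05) {
  x <- curve$elongation_mm
  y <- curve$load_N
  n <- length(x)
  if (n < 6L) abort("need at least 6 samples to fit a bilinear curve.")
  if (diff(range(y)) == 0) abort("constant (degenerate) curve.")
  rss_at <- function(cc) {
    X <- cbind(1, x, pmax(x - cc, 0))
    fit <- .lm.fit(X, y)
    sum(fit$residuals^2)
  }
  # candidate breakpoints: interior sample points with >= 2 points per side
  cand <- x[3:(n - 2)]
  cand <- cand[cand > x[1] & cand < x[n]]
  rss <- vapply(cand, rss_at, numeric(1))
  best <- which.min(rss)
  cc <- cand[best]
  if (refine) {
    lo <- if (best > 1L) cand[best - 1L] else x[1]
    hi <- if (best < length(cand)) cand[best + 1L] else x[n]
    op <- optimize(rss_at, c(lo, hi), tol = 1e-9)
    if (op$objective < rss[best]) cc <- op$minimum
  }
  X <- cbind(1, x, pmax(x - cc, 0))
  fit <- .lm.fit(X, y)
  beta <- coef(fit)
  toe <- beta[2]
  lin <- beta[2] + beta[3]
  rel <- abs(lin - toe) / max(abs(lin), abs(toe), .Machine$double.eps)
  structure(
    list(toe_slope = unname(toe), linear_slope = unname(lin),
         breakpoint_mm = unname(cc), rss = sum(fit$residuals^2),
         distinct_toe = rel > distinct_tol, n = n),
    class = "bilinear_fit"
  )
}

#' @export
print.bilinear_fit <- function(x, ...) {
  cat(sprintf(
    "<bilinear_fit> toe %.3g N/mm, linear %.3g N/mm, breakpoint %.3g mm (RSS %.3g)%s\n",
    x$toe_slope, x$linear_slope, x$breakpoint_mm, x$rss,
    if (x$distinct_toe) "" else " [no distinct toe region]"
  ))
  invisible(x)
}

#' Coefficients of a bilinear stiffness fit
#' @param x a `bilinear_fit`.
#' @param ... unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.bilinear_fit <- function(x, ...) {
  tibble(
    term = c("toe_slope", "linear_slope", "breakpoint_mm"),
    estimate = c(x$toe_slope, x$linear_slope, x$breakpoint_mm)
  )
}

#' One-row summary of a bilinear stiffness fit
#' @param x a `bilinear_fit`.
#' @param ... unused.
#' @return Tibble with slopes, breakpoint, RSS and the toe-region flag.
#' @export
glance.bilinear_fit <- function(x, ...) {
  tibble(toe_slope = x$toe_slope, linear_slope = x$linear_slope,
         breakpoint_mm = x$breakpoint_mm, rss = x$rss,
         distinct_toe = x$distinct_toe, n = x$n)
}

#' Compare two groups of curves by confidence-interval separation
#'
#' Two mesh groups differ significantly at an elongation where their 95%
#' confidence intervals do not overlap. Reports the per-grid-point
#' verdict and the sustained-separation onset: the smallest grid
#' elongation from which every subsequent point is significant (`NA` if
#' separation is never sustained to the end of the grid).
#'
#' @param curves_a,curves_b lists of `tensile_curve`s (>= 2 each).
#' @param grid elongation grid (mm); default 50 points across the common
#'   support of both groups.
#' @param conf confidence level (default 0.95).
#' @return Tibble of class `curve_comparison` with per-point columns
#'   `elongation_mm`, `mean_a`, `lo_a`, `hi_a`, `mean_b`, `lo_b`, `hi_b`,
#'   `significant`; attribute `onset_mm`.
#' @export
compare_curves <- function(curves_a, curves_b, grid = NULL, conf = 0.95) {
  if (length(curves_a) < 2L || length(curves_b) < 2L) {
    abort("both groups need at least 2 curves.")
  }
  if (is.null(grid)) {
    lo <- max(vapply(c(curves_a, curves_b),
                     function(cv) min(cv$elongation_mm), numeric(1)))
    hi <- min(vapply(c(curves_a, curves_b),
                     function(cv) max(cv$elongation_mm), numeric(1)))
    grid <- seq(lo, hi, length.out = 50L)
  }
  a <- average_curve(curves_a, grid, conf)
  b <- average_curve(curves_b, grid, conf)
  signif <- a$ci_lo > b$ci_hi | b$ci_lo > a$ci_hi
  # sustained separation: last run of TRUE reaching the grid end
  onset <- NA_real_
  if (length(signif) && signif[length(signif)]) {
    last_false <- max(c(0L, which(!signif)))
    onset <- grid[last_false + 1L]
  }
  structure(
    tibble(elongation_mm = grid,
           mean_a = a$mean_load_N, lo_a = a$ci_lo, hi_a = a$ci_hi,
           mean_b = b$mean_load_N, lo_b = b$ci_lo, hi_b = b$ci_hi,
           significant = signif),
    onset_mm = onset, conf = conf,
    class = c("curve_comparison", class(tibble())))
}

#' Sustained-separation onset of a curve comparison
#' @param x a `curve_comparison` from [compare_curves()].
#' @return Elongation (mm) from which the groups stay separated, or `NA`.
#' @export
separation_onset <- function(x) attr(x, "onset_mm")
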
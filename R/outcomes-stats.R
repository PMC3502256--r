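#' Mesh contraction as a percentage of the implanted size
#'
#' Contraction compares the explanted mesh size with the implanted size.
#' In `"area"` mode (default) size is length x width and the result is
#' `100 * (1 - explant_area / original_area)`; in `"linear"` mode it is
#' `100 * (1 - mean(explant_dim / original_dim))` over the two
#' dimensions. An explant larger than `plausibility_ratio` times the
#' original (area ratio) is rejected as a measurement error.
#'
#' @param original_length_mm,original_width_mm implanted mesh dimensions
#'   (mm, > 0).
#' @param explant_length_mm,explant_width_mm explanted mesh dimensions
#'   (mm, > 0).
#' @param mode `"area"` (default) or `"linear"`.
#' @param plausibility_ratio maximum credible explant/original area ratio
#'   (default 1.2).
#' @return Contraction in percent (negative values mean growth),
#'   vectorized.
#' @export
contraction_percent <- function(original_length_mm, original_width_mm,
                                explant_length_mm, explant_width_mm,
                                mode = c("area", "linear"),
                                plausibility_ratio = 1.2) {
  mode <- match.arg(mode)
  dims <- c(original_length_mm, original_width_mm,
            explant_length_mm, explant_width_mm)
  if (any(dims <= 0)) abort("all mesh dimensions must be > 0.")
  ratio <- (explant_length_mm * explant_width_mm) /
    (original_length_mm * original_width_mm)
  if (any(ratio > plausibility_ratio)) {
    abort("explant exceeds the plausibility bound; check the measurements.")
  }
  if (mode == "area") {
    100 * (1 - ratio)
  } else {
    100 * (1 - (explant_length_mm / original_length_mm +
                explant_width_mm / original_width_mm) / 2)
  }
}

#' Adhesion area as a percentage of total mesh area
#'
#' @param adhesion_mm2 area of visceral adhesion on the mesh (mm^2, >= 0).
#' @param mesh_mm2 total mesh area (mm^2, > 0).
#' @return `100 * adhesion / mesh`, vectorized.
#' @export
adhesion_area_percent <- function(adhesion_mm2, mesh_mm2) {
  if (any(mesh_mm2 <= 0)) abort("`mesh_mm2` must be > 0.")
  if (any(adhesion_mm2 < 0)) abort("`adhesion_mm2` must be >= 0.")
  if (any(adhesion_mm2 > mesh_mm2)) {
    abort("adhesion area cannot exceed the mesh area.")
  }
  100 * adhesion_mm2 / mesh_mm2
}

#' Per-animal body-weight gain relative to baseline
#'
#' @param data tibble with columns `animal`, `timepoint`, `weight`.
#' @param baseline_timepoint timepoint taken as baseline; default the
#'   earliest timepoint of each animal. Animals lacking the baseline
#'   raise an error.
#' @param relative report gain as percent of baseline (default absolute
#'   grams).
#' @return Input rows with added `baseline` and `gain` columns.
#' @export
weight_gain <- function(data, baseline_timepoint = NULL, relative = FALSE) {
  data <- as_tibble(data)
  need <- c("animal", "timepoint", "weight")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns animal, timepoint, weight.")
  }
  pick_baseline <- function(timepoint, weight) {
    if (is.null(baseline_timepoint)) return(weight[which.min(timepoint)])
    hit <- which(timepoint == baseline_timepoint)
    if (length(hit) == 0L) NA_real_ else weight[hit[1]]
  }
  base <- data %>%
    group_by(.data$animal) %>%
    summarise(baseline = pick_baseline(.data$timepoint, .data$weight),
              .groups = "drop")
  if (anyNA(base$baseline)) {
    abort(sprintf("baseline timepoint missing for animal(s): %s",
                  paste(base$animal[is.na(base$baseline)], collapse = ", ")))
  }
  out <- left_join(data, base, by = "animal")
  out$gain <- if (relative) {
    100 * (out$weight - out$baseline) / out$baseline
  } else {
    out$weight - out$baseline
  }
  out
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) Z-scores into K^2 = Z1^2 + Z2^2, chi-squared with 2
#' df under normality. Requires n >= 8.
#'
#' @param x numeric vector (n >= 8, non-constant).
#' @return Tibble with `statistic` (K^2), `p_value`, `z_skew`, `z_kurt`,
#'   `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) abort("D'Agostino-Pearson test requires n >= 8.")
  if (sd(x) == 0) abort("constant sample: normality test undefined.")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness component (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis component (Anscombe-Glynn 1983)
  k2 <- m4 / m2^2
  e_b2 <- 3 * (n - 1) / (n + 1)
  v_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (k2 - e_b2) / sqrt(v_b2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  stat <- z1^2 + z2^2
  tibble(statistic = stat,
         p_value = pchisq(stat, df = 2, lower.tail = FALSE),
         z_skew = z1, z_kurt = z2, n = n)
}

#' Nonparametric group comparison of an outcome
#'
#' The standard engine for per-animal outcomes: a per-group
#' D'Agostino-Pearson normality check (reported, not gating; `NA` for
#' groups below n = 8), a tie-corrected Kruskal-Wallis omnibus test
#' across groups, and all pairwise two-sided rank-sum (Wilcoxon)
#' comparisons with Bonferroni correction, where the multiplier m is the
#' number of pairwise comparisons actually performed.
#'
#' @param data tibble with at least columns `group` and `value`; when
#'   `outcome` / `timepoint` are given and matching columns exist, rows
#'   are filtered to them first.
#' @param outcome optional outcome name to filter on.
#' @param timepoint optional timepoint to filter on.
#' @param alpha significance level (default 0.05).
#' @return An object of class `group_comparison`.
#' @export
compare_groups <- function(data, outcome = NULL, timepoint = NULL,
                           alpha = 0.05) {
  data <- as_tibble(data)
  if (!is.null(outcome) && "outcome" %in% names(data)) {
    data <- data[data$outcome == outcome, , drop = FALSE]
  }
  if (!is.null(timepoint) && "timepoint" %in% names(data)) {
    data <- data[data$timepoint == timepoint, , drop = FALSE]
  }
  if (!all(c("group", "value") %in% names(data))) {
    abort("`data` needs columns group, value.")
  }
  data <- data[is.finite(data$value), , drop = FALSE]
  grp <- factor(data$group)
  counts <- table(grp)
  if (length(counts) < 2L) abort("need at least 2 groups.")
  if (any(counts < 3L)) abort("every group needs at least 3 values.")
  normality <- bind_rows(lapply(levels(grp), function(g) {
    v <- data$value[grp == g]
    if (length(v) >= 8L && sd(v) > 0) {
      dp <- dagostino_pearson(v)
      tibble(group = g, n = length(v), k2 = dp$statistic,
             p_normal = dp$p_value)
    } else {
      tibble(group = g, n = length(v), k2 = NA_real_, p_normal = NA_real_)
    }
  }))
  if (stats::var(data$value) == 0) {
    omnibus <- tibble(statistic = 0, df = length(counts) - 1L, p_value = 1)
  } else {
    kw <- kruskal.test(data$value, grp)
    omnibus <- tibble(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value)
  }
  pairs <- utils::combn(levels(grp), 2L)
  raw <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- data$value[grp == pairs[1, j]]
    b <- data$value[grp == pairs[2, j]]
    if (length(unique(c(a, b))) == 1L) return(1)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  pairwise <- tibble(
    group_a = pairs[1, ], group_b = pairs[2, ],
    n_a = as.integer(counts[pairs[1, ]]),
    n_b = as.integer(counts[pairs[2, ]]),
    p_raw = raw,
    p_adj = p.adjust(raw, method = "bonferroni"),
    significant = p.adjust(raw, method = "bonferroni") < alpha
  )
  structure(
    list(omnibus = omnibus, pairwise = pairwise, normality = normality,
         alpha = alpha, m = ncol(pairs)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> Kruskal-Wallis H = %.3f (df = %d), p = %.3g; %d pairwise comparisons (Bonferroni m = %d)\n",
    x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value,
    nrow(x$pairwise), x$m
  ))
  print(x$pairwise)
  invisible(x)
}

#' Pairwise comparisons of a group comparison
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return Tibble of group pairs with raw and Bonferroni-adjusted
#'   p-values.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' One-row summary of a group comparison
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return Tibble with the omnibus statistic and p-value, the Bonferroni
#'   multiplier and the number of significant pairs.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    statistic = x$omnibus$statistic, df = x$omnibus$df,
    p_value = x$omnibus$p_value, m = x$m,
    n_significant_pairs = sum(x$pairwise$significant)
  )
}
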
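#' Plot a band profile
#'
#' Positive-area fraction against distance band, the standard way to
#' display the peri-filament staining gradient.
#'
#' @param object a `band_profile`.
#' @param percent plot percent positive area instead of a fraction.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.band_profile <- function(object, percent = FALSE, ...) {
  df <- as_tibble(object)
  df$y <- if (percent) 100 * df$fraction else df$fraction
  df$interval <- sprintf("%g-%g", df$band_lo_um, df$band_hi_um)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$interval, .data$band), y = .data$y)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "Distance from filament surface (µm)",
      y = if (percent) "Positive area (%)" else "Positive area fraction"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an averaged load-elongation curve with its confidence envelope
#'
#' @param object an `average_curve` from [average_curve()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.average_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$elongation_mm,
                                       .data$mean_load_N)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Elongation (mm)", y = "Load (N)") +
    ggplot2::theme_minimal()
}

#' Plot a two-group curve comparison
#'
#' Both mean curves with confidence envelopes; elongations where the
#' envelopes separate are marked along the axis.
#'
#' @param object a `curve_comparison` from [compare_curves()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.curve_comparison <- function(object, ...) {
  df <- as_tibble(object)
  long <- bind_rows(
    tibble(elongation_mm = df$elongation_mm, group = "A",
           mean = df$mean_a, lo = df$lo_a, hi = df$hi_a),
    tibble(elongation_mm = df$elongation_mm, group = "B",
           mean = df$mean_b, lo = df$lo_b, hi = df$hi_b)
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$elongation_mm, .data$mean,
                                          colour = .data$group,
                                          fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Elongation (mm)", y = "Load (N)") +
    ggplot2::theme_minimal()
  sig <- df[df$significant, , drop = FALSE]
  if (nrow(sig) > 0L) {
    p <- p + ggplot2::geom_rug(
      data = sig, ggplot2::aes(x = .data$elongation_mm),
      inherit.aes = FALSE, sides = "b")
  }
  p
}

#' Plot a gradient test result
#'
#' Per-animal fractions by band with the band medians, annotated with the
#' omnibus verdict.
#'
#' @param object a `gradient_result`; needs the `profiles` used to build
#'   it, passed as `profiles`.
#' @param profiles the tibble given to [gradient_test()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gradient_result <- function(object, profiles, ...) {
  ggplot2::ggplot(profiles, ggplot2::aes(factor(.data$band),
                                         .data$fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(
      x = "Band index (50 µm increments)",
      y = "Positive area fraction",
      subtitle = sprintf("Kruskal-Wallis p = %.3g; %s",
                         object$omnibus$p_value,
                         if (object$gradient) "diminishing gradient"
                         else "no gradient")
    ) +
    ggplot2::theme_minimal()
}
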
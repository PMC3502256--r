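#' Generate a synthetic per-animal outcome table
#'
#' Draws one continuous outcome value per animal for every group x
#' timepoint cell, from a Gaussian with the cell's location and scale.
#' This mirrors the design of the in-vivo study: a small number of mesh
#' groups, four explant timepoints, six animals per cell.
#'
#' @param design tibble with one row per group x timepoint cell and
#'   columns `group`, `timepoint`, `location`, `scale` (>= 0) and
#'   optionally `n` (animals per cell; default `n_per_cell`).
#' @param n_per_cell default number of animals per cell (>= 1).
#' @param outcome name of the outcome column recorded in the table.
#' @param seed integer seed.
#' @return A tibble with columns `animal`, `group`, `timepoint`,
#'   `outcome`, `value`; one row per animal x cell.
#' @export
generate_group_table <- function(design,
                                 n_per_cell = 6L,
                                 outcome = "outcome",
                                 seed = NULL) {
  design <- as_tibble(design)
  need <- c("group", "timepoint", "location", "scale")
  if (!all(need %in% names(design))) {
    abort("`design` needs columns group, timepoint, location, scale.")
  }
  if (!("n" %in% names(design))) design$n <- as.integer(n_per_cell)
  if (any(design$n < 1L)) abort("every cell needs n >= 1.")
  if (any(design$scale < 0)) abort("`scale` must be >= 0.")
  gen <- function() {
    rows <- purrr::pmap(design, function(group, timepoint, location, scale, n) {
      tibble(
        animal = paste0(group, "_d", timepoint, "_", seq_len(n)),
        group = group,
        timepoint = timepoint,
        outcome = outcome,
        value = location + scale * rnorm(n)
      )
    })
    bind_rows(rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
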
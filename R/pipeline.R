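#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], populated
#' with the study's standard conditions: 6 animals per group, 4 analysed
#' fields per animal, 50 um band increments with 4 bands, 14 mm gauge
#' length, 100 mN pre-load, 0.05 significance level.
#'
#' @param out_dir optional output directory; `NULL` keeps everything in
#'   memory.
#' @param seed integer seed driving every stochastic stage.
#' @return A `run_config` list.
#' @export
default_run_config <- function(out_dir = NULL, seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    px_size_um = 2,
    image_px = 256L,
    increment_um = 50,
    n_bands = 4L,
    n_animals = 6L,
    images_per_animal = 4L,
    gauge_mm = 14,
    preload_N = 0.1,
    alpha = 0.05,
    markers = list(
      cd68 = list(stain_mode = "brightfield_dab", marker = "dab",
                  p0 = 0.8, lambda_um = 50, floor = 0.05, noise_sd = 0.02),
      cd31 = list(stain_mode = "fluorescence", marker = "fluor",
                  p0 = 0.25, lambda_um = Inf, floor = 0.25, noise_sd = 0.02)
    ),
    tensile = list(
      day7 = list(toe_slope = 0.5, linear_slope = 1.7, breakpoint_mm = 1.7,
                  noise_sd_N = 0.05, n_samples = 10L, max_elongation_mm = 6),
      day90 = list(toe_slope = 0.8, linear_slope = 5.1, breakpoint_mm = 0.9,
                   noise_sd_N = 0.05, n_samples = 10L, max_elongation_mm = 6)
    ),
    outcomes = tibble(
      group = rep(c("PA", "PEEK", "PP"), each = 1L),
      timepoint = 30,
      location = c(20, 10, 25),
      scale = 4
    )
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys override the defaults of
#' [default_run_config()]; unknown keys raise an error before any
#' computation.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  if (!is.null(cfg$outcomes)) cfg$outcomes <- as_tibble(cfg$outcomes)
  validate_run_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg a `run_config` list.
#' @return `cfg`, invisibly usable, after checking every numeric
#'   parameter is positive, the significance level lies in (0, 1) and all
#'   marker names are recognised.
#' @export
validate_run_config <- function(cfg) {
  num <- c("px_size_um", "image_px", "increment_um", "n_bands", "n_animals",
           "images_per_animal", "gauge_mm", "preload_N")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0) {
      abort(sprintf("config field `%s` must be a single positive number.", k))
    }
  }
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    abort("config field `alpha` must lie in (0, 1).")
  }
  for (nm in names(cfg$markers)) analysis_mode(nm) # errors on unknown marker
  cfg
}

measure_band_profile <- function(img, marker, increment_um, n_bands) {
  fil <- binarize_filaments(img)
  if (!isTRUE(attr(fil, "filament_detected"))) {
    abort("no filament detected in a generated field.")
  }
  bundles <- label_bundles(fil, img$px_size_um)
  bundles <- suppressWarnings(select_central_bundles(bundles, k = 4L))
  bands <- build_bands(bundles, increment_um = increment_um,
                       n_bands = n_bands)
  pos <- positive_mask(img, marker, filament_mask = fil)
  band_fractions(bands, pos, tissue = !fil)
}

#' Run the full synthetic-study pipeline
#'
#' Executes the analysis chain end to end on generated data: for every
#' configured marker, simulate per-animal micrograph fields, segment the
#' filaments, build distance bands, measure band and whole-image
#' positive fractions, and (for near-filament markers) test for a
#' diminishing gradient; generate and analyse tensile curves per group
#' (pre-load trim, failure trim, bilinear stiffness fit, averaged curves,
#' CI comparison); generate the outcome table and run the group
#' comparison. Identical seeds give identical reports. When
#' `cfg$out_dir` is set, per-stage CSV/JSON outputs and a manifest (with
#' a config hash and the seed) are written there.
#'
#' @param cfg a `run_config`, e.g. [default_run_config()].
#' @return A list of class `periband_report` with elements `histology`
#'   (per-marker profiles, headline values, gradient results), `biomech`
#'   (per-group fits, average curves, comparison), `outcomes`
#'   (group comparison) and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_run_config(cfg)
  seed <- cfg$seed
  histology <- purrr::imap(cfg$markers, function(mk, name) {
    scene <- histology_scene(
      width_px = cfg$image_px, height_px = cfg$image_px,
      px_size_um = cfg$px_size_um,
      filaments = bundle_layout(1L, 3L, r_um = 50,
                                width_um = cfg$image_px * cfg$px_size_um,
                                height_um = cfg$image_px * cfg$px_size_um),
      stain_mode = mk$stain_mode, p0 = mk$p0, lambda_um = mk$lambda_um,
      floor = mk$floor, noise_sd = mk$noise_sd
    )
    offset <- match(name, names(cfg$markers)) * 10000L
    profiles <- purrr::map(seq_len(cfg$n_animals), function(a) {
      per_image <- purrr::map(seq_len(cfg$images_per_animal), function(i) {
        sim <- generate_histology(scene, seed = seed + offset +
                                    a * 100L + i)
        prof <- measure_band_profile(sim$image, mk$marker,
                                     cfg$increment_um, cfg$n_bands)
        mutate(as_tibble(prof), whole = attr(prof, "whole_fraction"))
      })
      bind_rows(per_image) %>%
        group_by(.data$band) %>%
        summarise(fraction = mean(.data$fraction),
                  whole = mean(.data$whole), .groups = "drop") %>%
        mutate(animal = a)
    })
    profiles <- bind_rows(profiles)
    mode <- analysis_mode(name)
    headline <- if (mode == "near_filament") {
      mean(profiles$fraction[profiles$band == 1L])
    } else {
      mean(profiles$whole[profiles$band == 1L])
    }
    grad <- if (mode == "near_filament") {
      gradient_test(profiles[, c("animal", "band", "fraction")],
                    alpha = cfg$alpha)
    } else {
      NULL
    }
    list(marker = name, mode = mode, profiles = profiles,
         headline_fraction = headline, gradient = grad)
  })
  biomech_groups <- purrr::imap(cfg$tensile, function(tp, name) {
    truth <- tensile_truth(tp$toe_slope, tp$linear_slope, tp$breakpoint_mm,
                           gauge_mm = cfg$gauge_mm,
                           noise_sd_N = tp$noise_sd_N)
    offset <- match(name, names(cfg$tensile)) * 1000L
    curves <- purrr::map(seq_len(tp$n_samples), function(i) {
      generate_tensile(truth, n_points = 120L,
                       max_elongation_mm = tp$max_elongation_mm,
                       seed = seed + offset + i) %>%
        trim_preload(cfg$preload_N) %>%
        trim_failure()
    })
    fits <- purrr::map(curves, fit_bilinear)
    list(name = name, curves = curves,
         fits = bind_rows(purrr::map(fits, glance)),
         average = average_curve(curves))
  })
  comparison <- if (length(biomech_groups) >= 2L) {
    compare_curves(biomech_groups[[1]]$curves, biomech_groups[[2]]$curves)
  } else {
    NULL
  }
  outcomes <- NULL
  if (!is.null(cfg$outcomes) && nrow(cfg$outcomes) >= 2L) {
    tab <- generate_group_table(cfg$outcomes, n_per_cell = cfg$n_animals,
                                outcome = "outcome", seed = seed + 999L)
    outcomes <- list(table = tab,
                     comparison = compare_groups(tab, alpha = cfg$alpha))
  }
  report <- structure(
    list(
      histology = histology,
      biomech = list(groups = biomech_groups, comparison = comparison),
      outcomes = outcomes,
      manifest = list(
        seed = seed,
        config_hash = rlang::hash(cfg),
        package_version = as.character(utils::packageVersion("periband")),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "periband_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.periband_report <- function(x, ...) {
  cat("<periband_report>\n")
  for (h in x$histology) {
    cat(sprintf("  marker %s (%s): headline fraction %.3f%s\n",
                h$marker, h$mode, h$headline_fraction,
                if (!is.null(h$gradient) && h$gradient$gradient)
                  ", diminishing gradient" else ""))
  }
  for (g in x$biomech$groups) {
    cat(sprintf("  tensile %s: median linear slope %.2f N/mm\n",
                g$name, median(g$fits$linear_slope)))
  }
  if (!is.null(x$biomech$comparison)) {
    cat(sprintf("  curve separation onset: %s mm\n",
                format(separation_onset(x$biomech$comparison))))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes per-marker band profiles and tensile results as CSV, the
#' statistical summaries and manifest as JSON.
#'
#' @param report a `periband_report`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (h in report$histology) {
    readr::write_csv(h$profiles,
                     file.path(dir, sprintf("profiles_%s.csv", h$marker)))
  }
  for (g in report$biomech$groups) {
    readr::write_csv(g$fits, file.path(dir, sprintf("fits_%s.csv", g$name)))
    readr::write_csv(as_tibble(g$average),
                     file.path(dir, sprintf("average_%s.csv", g$name)))
  }
  summary <- list(
    manifest = report$manifest,
    gradients = purrr::compact(purrr::map(report$histology, function(h) {
      if (is.null(h$gradient)) return(NULL)
      as.list(glance(h$gradient))
    })),
    outcomes = if (!is.null(report$outcomes)) {
      as.list(glance(report$outcomes$comparison))
    }
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write / read a band-profile table as CSV
#'
#' The CSV round-trips the per-band rows and the whole-image attributes
#' (kept in extra columns), so `read_band_profile(write_band_profile(x))`
#' reproduces `x`.
#'
#' @param profile a `band_profile`.
#' @param path CSV path.
#' @return `path` (writer) / a `band_profile` (reader).
#' @export
write_band_profile <- function(profile, path) {
  df <- as_tibble(profile)
  df$whole_fraction <- attr(profile, "whole_fraction")
  df$whole_tissue_px <- attr(profile, "whole_tissue_px")
  df$whole_positive_px <- attr(profile, "whole_positive_px")
  df$increment_um <- attr(profile, "increment_um")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_band_profile
#' @export
read_band_profile <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- df[, c("band", "band_lo_um", "band_hi_um", "tissue_px",
                "positive_px", "fraction")]
  out$band <- as.integer(out$band)
  out$tissue_px <- as.integer(out$tissue_px)
  out$positive_px <- as.integer(out$positive_px)
  structure(out,
            whole_fraction = df$whole_fraction[1],
            whole_tissue_px = as.integer(df$whole_tissue_px[1]),
            whole_positive_px = as.integer(df$whole_positive_px[1]),
            increment_um = df$increment_um[1],
            class = c("band_profile", class(out)))
}

#' Write / read a tensile curve as CSV with a metadata header
#'
#' The gauge length, pre-load and trim state travel in `#`-prefixed
#' header lines above the `elongation_mm,load_N` records.
#'
#' @param curve a `tensile_curve`.
#' @param path CSV path.
#' @return `path` (writer) / a `tensile_curve` (reader).
#' @export
write_tensile_curve <- function(curve, path) {
  hdr <- c(
    sprintf("# gauge_mm: %.17g", gauge_length(curve)),
    sprintf("# preload_N: %.17g", attr(curve, "preload_N") %||% NA_real_),
    sprintf("# trimmed: %s", isTRUE(attr(curve, "trimmed")))
  )
  writeLines(hdr, path)
  readr::write_csv(as_tibble(curve), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_tensile_curve
#' @export
read_tensile_curve <- function(path) {
  hdr <- readLines(path, n = 3L)
  val <- function(i) sub("^# [A-Za-z_]+: ", "", hdr[i])
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  new_tensile_curve(df,
                    gauge_mm = as.numeric(val(1)),
                    preload_N = as.numeric(val(2)),
                    trimmed = identical(val(3), "TRUE"))
}
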
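test_that("strain reproduces the reported worked examples at 2 s.f.", {
  expect_equal(strain_percent(0.9, 14), 6.4)
  expect_equal(strain_percent(2.0, 14), 14)
  expect_equal(strain_percent(0, 14), 0)
  expect_equal(strain_percent(14, 14), 100)
  expect_equal(strain_percent(0.9, 14, signif = NULL), 100 * 0.9 / 14)
  expect_error(strain_percent(-1, 14), "elongation")
  expect_error(strain_percent(1, 0), "gauge")
})

test_that("strain is linear and scale-consistent", {
  x <- runif(20, 0, 5)
  g <- 14
  expect_equal(strain_percent(3 * x, 3 * g, signif = NULL),
               strain_percent(x, g, signif = NULL))
  expect_equal(strain_percent(2 * x, g, signif = NULL),
               2 * strain_percent(x, g, signif = NULL))
})

test_that("pre-load trimming re-zeroes at the interpolated crossing", {
  k <- 0.8
  cv <- generate_tensile(tensile_truth(k, k, 1, noise_sd_N = 0), 101, 4)
  tv <- trim_preload(cv, 0.1)
  # closed form: crossing at x = 0.1 / k; loads restart at the pre-load
  expect_equal(tv$load_N[1], 0.1)
  expect_equal(tv$elongation_mm[1], 0)
  expect_equal(max(cv$elongation_mm) - max(tv$elongation_mm), 0.1 / k)
  expect_true(isTRUE(attr(tv, "trimmed")))
  # idempotence
  expect_identical(trim_preload(tv, 0.1), tv)
  # a curve already above the pre-load is only re-zeroed
  above <- new_curve_for_test(seq(2, 4, by = 0.5), seq(1, 3, by = 0.5))
  ta <- trim_preload(above, 0.1)
  expect_equal(ta$elongation_mm[1], 0)
  expect_equal(nrow(ta), nrow(above))
  expect_equal(ta$load_N, above$load_N)
  # all-zero loads never reach the pre-load
  zero <- new_curve_for_test(0:5, rep(0, 6))
  expect_error(trim_preload(zero), "never reaches")
})

test_that("failure trimming cuts after the peak load", {
  x <- seq(0, 5, length.out = 21)
  y <- c(seq(0, 4, length.out = 17), 3, 2, 1, 0.5)
  cv <- new_curve_for_test(x, y)
  tf <- trim_failure(cv)
  expect_equal(nrow(tf), 17L)
  expect_equal(max(tf$load_N), 4)
})

test_that("curve averaging gives exact means and degenerate zero-width CIs", {
  tr <- tensile_truth(0.5, 2, 1.5, noise_sd_N = 0)
  cv <- generate_tensile(tr, 60, 4)
  avg <- average_curve(list(cv, cv, cv))
  expect_equal(avg$ci_lo, avg$mean_load_N)
  expect_equal(avg$ci_hi, avg$mean_load_N)
  # two curves: the mean is the pointwise midpoint
  cv2 <- generate_tensile(tensile_truth(1, 3, 1.5, noise_sd_N = 0), 60, 4)
  grid <- seq(0.2, 3.5, length.out = 25)
  avg2 <- average_curve(list(cv, cv2), grid = grid)
  y1 <- approx(cv$elongation_mm, cv$load_N, grid)$y
  y2 <- approx(cv2$elongation_mm, cv2$load_N, grid)$y
  expect_equal(avg2$mean_load_N, (y1 + y2) / 2)
  expect_error(average_curve(list(cv)), "at least 2")
  expect_error(average_curve(list(cv, cv2), grid = c(-1, 2)), "support")
})

test_that("noiseless bilinear curves are recovered exactly", {
  tr <- tensile_truth(0.5, 5.0, 1.7, noise_sd_N = 0)
  cv <- generate_tensile(tr, 100, 4)
  fit <- fit_bilinear(cv)
  expect_equal(fit$toe_slope, 0.5, tolerance = 1e-6)
  expect_equal(fit$linear_slope, 5.0, tolerance = 1e-6)
  expect_equal(fit$breakpoint_mm, 1.7, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_true(fit$distinct_toe)
  expect_equal(tidy(fit)$estimate,
               c(fit$toe_slope, fit$linear_slope, fit$breakpoint_mm))
})

test_that("a straight line is flagged as having no distinct toe region", {
  cv <- generate_tensile(tensile_truth(2, 2, 1, noise_sd_N = 0), 50, 4)
  fit <- fit_bilinear(cv)
  expect_false(fit$distinct_toe)
  expect_equal(fit$toe_slope, fit$linear_slope, tolerance = 1e-6)
  expect_error(fit_bilinear(new_curve_for_test(0:9, rep(1, 10))),
               "degenerate")
  expect_error(fit_bilinear(new_curve_for_test(0:4, 0:4)), "6 samples")
})

test_that("grid fit equals the exhaustive-breakpoint oracle on short curves", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    tr <- tensile_truth(runif(1, 0, 1), runif(1, 1.5, 6), runif(1, 0.8, 2),
                        noise_sd_N = 0.05)
    cv <- generate_tensile(tr, n, 4, seed = i)
    fit <- fit_bilinear(cv, refine = FALSE)
    # oracle: try every interior sample point with plain lm()
    x <- cv$elongation_mm; y <- cv$load_N
    cand <- x[3:(n - 2)]
    rss <- vapply(cand, function(cc) {
      sum(resid(lm(y ~ x + pmax(x - cc, 0)))^2)
    }, numeric(1))
    expect_equal(fit$breakpoint_mm, cand[which.min(rss)])
    expect_equal(fit$rss, min(rss), tolerance = 1e-8)
  }
})

test_that("stiffer populations yield larger fitted linear slopes", {
  slopes <- c(1.5, 3, 6)
  fitted <- vapply(seq_along(slopes), function(i) {
    tr <- tensile_truth(0.5, slopes[i], 1.2, noise_sd_N = 0.05)
    median(vapply(1:5, function(j) {
      fit_bilinear(generate_tensile(tr, 80, 4, seed = 100 * i + j))$linear_slope
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("identical groups never separate; distant groups always do", {
  tr <- tensile_truth(0.5, 2, 1.5, noise_sd_N = 0.02)
  ga <- lapply(1:4, function(i) generate_tensile(tr, 60, 4, seed = i))
  cmp_same <- compare_curves(ga, ga)
  expect_false(any(cmp_same$significant))
  expect_true(is.na(separation_onset(cmp_same)))
  # offset far beyond the CI width: significant everywhere from the start
  tr_hi <- tensile_truth(0.5, 2, 1.5, noise_sd_N = 0.02)
  gb <- lapply(ga, function(cv) {
    new_curve_for_test(cv$elongation_mm, cv$load_N + 50)
  })
  cmp_far <- compare_curves(ga, gb)
  expect_true(all(cmp_far$significant))
  expect_equal(separation_onset(cmp_far), cmp_far$elongation_mm[1])
  expect_error(compare_curves(ga, list(ga[[1]])), "at least 2")
})
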
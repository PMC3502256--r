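test_that("contraction arithmetic matches direct computation", {
  expect_equal(contraction_percent(25, 35, 25, 35), 0)
  # half the area -> 50% contraction
  expect_equal(contraction_percent(20, 30, 20, 15), 50)
  expect_equal(contraction_percent(25, 35, 22, 31),
               100 * (1 - 682 / 875))
  expect_equal(round(contraction_percent(25, 35, 22, 31), 2), 22.06)
  # linear mode averages the per-dimension shrinkage
  expect_equal(contraction_percent(25, 35, 22, 31, mode = "linear"),
               100 * (1 - (22 / 25 + 31 / 35) / 2))
  expect_error(contraction_percent(25, 35, 40, 40), "plausibility")
  expect_error(contraction_percent(0, 35, 22, 31), "> 0")
})

test_that("adhesion area percentage is plain arithmetic with guards", {
  expect_equal(adhesion_area_percent(875, 875), 100)
  expect_equal(adhesion_area_percent(0, 875), 0)
  expect_equal(adhesion_area_percent(700, 875), 80)
  expect_error(adhesion_area_percent(900, 875), "exceed")
  expect_error(adhesion_area_percent(10, 0), "> 0")
})

test_that("weight gain is computed against each animal's baseline", {
  d <- tidyr::expand_grid(animal = c("r1", "r2"), timepoint = c(0, 30, 90))
  d$weight <- c(250, 260, 280, 240, 240, 240)
  g <- weight_gain(d)
  expect_equal(g$gain[g$animal == "r1"], c(0, 10, 30))
  expect_equal(g$gain[g$animal == "r2"], c(0, 0, 0))
  rel <- weight_gain(d, relative = TRUE)
  expect_equal(rel$gain[rel$animal == "r1" & rel$timepoint == 90],
               100 * 30 / 250)
  # monotone weights give monotone gains
  expect_true(all(diff(g$gain[g$animal == "r1"]) >= 0))
  expect_error(weight_gain(d, baseline_timepoint = 7), "missing")
})

test_that("D'Agostino-Pearson matches frozen reference values", {
  # references computed once with an independent implementation of the
  # same published formulas (scipy.stats.normaltest)
  x20 <- c(10.609434, 7.920032, 11.500902, 11.881129, 6.09793, 7.395641,
           10.255681, 9.367515, 9.966398, 8.293912, 11.758796, 11.555584,
           10.132061, 12.254482, 10.935019, 8.281415, 10.737502, 8.082235,
           11.756901, 9.900148)
  r <- dagostino_pearson(x20)
  expect_equal(r$statistic, 1.6864872489, tolerance = 1e-8)
  expect_equal(r$p_value, 0.4303124852, tolerance = 1e-8)
  expect_equal(r$z_skew, -1.2177454600, tolerance = 1e-8)
  expect_equal(r$z_kurt, -0.4512019986, tolerance = 1e-8)
  x15 <- c(1.247386, 0.223576, 1.83797, 1.227086, 0.655796, 0.417087,
           0.45332, 0.077077, 0.179632, 0.68532, 0.38868, 1.264207,
           0.708491, 0.23793, 0.461088)
  r2 <- dagostino_pearson(x15)
  expect_equal(r2$statistic, 3.4312165357, tolerance = 1e-8)
  expect_equal(r2$p_value, 0.1798542879, tolerance = 1e-8)
  x30 <- c(0.189471, 0.129922, 0.475705, 0.226909, 0.669814, 0.437152,
           0.832678, 0.700265, 0.312367, 0.83226, 0.804764, 0.387478,
           0.288328, 0.682496, 0.139752, 0.199908, 0.007362, 0.786924,
           0.664851, 0.705165, 0.780729, 0.458916, 0.568741, 0.139797,
           0.11453, 0.668403, 0.471096, 0.565236, 0.764999, 0.634718)
  r3 <- dagostino_pearson(x30)
  expect_equal(r3$statistic, 7.9884929143, tolerance = 1e-8)
  expect_equal(r3$z_kurt, -2.7237171932, tolerance = 1e-8)
  expect_error(dagostino_pearson(1:5), "n >= 8")
})

test_that("the worked rank example gives H = 7.2", {
  d <- tibble::tibble(group = rep(c("A", "B", "C"), each = 3),
                      value = 1:9)
  cmp <- compare_groups(d)
  expect_equal(cmp$omnibus$statistic, 7.2)
  expect_equal(cmp$omnibus$df, 2L)
})

test_that("identical values give p = 1 and no significant pairs", {
  d <- tibble::tibble(group = rep(c("A", "B", "C"), each = 4), value = 3)
  cmp <- compare_groups(d)
  expect_equal(cmp$omnibus$p_value, 1)
  expect_false(any(cmp$pairwise$significant))
  expect_true(all(cmp$pairwise$p_adj == 1))
})

test_that("Bonferroni adjustment is m * p capped at 1, order-preserving", {
  # the arithmetic the engine relies on: raw 0.004 with m = 10 -> 0.04
  expect_equal(p.adjust(c(0.004, rep(0.5, 9)), "bonferroni")[1], 0.04)
  d <- generate_group_table(
    tibble::tibble(group = LETTERS[1:5], timepoint = 30,
                   location = c(0, 1, 2, 3, 4), scale = 1),
    n_per_cell = 6, seed = 5
  )
  cmp <- compare_groups(d)
  expect_equal(cmp$m, 10L)
  expect_equal(cmp$pairwise$p_adj, pmin(1, 10 * cmp$pairwise$p_raw))
  # monotone in the raw p-values (ties from the cap at 1 allowed)
  expect_true(all(diff(cmp$pairwise$p_adj[order(cmp$pairwise$p_raw)]) >= 0))
  expect_true(all(cmp$pairwise$p_adj <= 1))
})

test_that("Kruskal-Wallis agrees with brute-force ranks on small inputs", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(6:15, 1)
    k <- sample(2:3, 1)
    g <- sample(rep(letters[1:k], length.out = n))
    # draw from a coarse grid so ties occur often
    v <- sample(1:6, n, replace = TRUE)
    if (any(table(g) < 3) || var(v) == 0) next
    cmp <- compare_groups(tibble::tibble(group = g, value = v))
    expect_equal(cmp$omnibus$statistic, bf_kruskal_H(v, g), tolerance = 1e-8)
  }
})

test_that("omnibus rejection under random relabelling is near nominal", {
  set.seed(123)
  base <- rnorm(18)
  rejections <- vapply(1:1000, function(i) {
    g <- sample(rep(c("A", "B", "C"), each = 6))
    kruskal.test(base, factor(g))$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("a 5-SD location shift at n = 6 per group is reliably detected", {
  hits <- vapply(1:200, function(i) {
    tab <- generate_group_table(
      tibble::tibble(group = c("A", "B"), timepoint = 7,
                     location = c(0, 5), scale = 1),
      n_per_cell = 6, seed = i
    )
    compare_groups(tab)$omnibus$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("group comparison filters by outcome and timepoint and validates", {
  tab <- dplyr::bind_rows(
    generate_group_table(tibble::tibble(group = c("PA", "PP"),
                                        timepoint = 7, location = c(0, 4),
                                        scale = 1),
                         outcome = "contraction", seed = 1),
    generate_group_table(tibble::tibble(group = c("PA", "PP"),
                                        timepoint = 90, location = c(0, 0),
                                        scale = 1),
                         outcome = "contraction", seed = 2)
  )
  c7 <- compare_groups(tab, outcome = "contraction", timepoint = 7)
  c90 <- compare_groups(tab, outcome = "contraction", timepoint = 90)
  expect_lt(c7$omnibus$p_value, 0.05)
  expect_gt(c90$omnibus$p_value, 0.05)
  expect_error(compare_groups(tab[tab$group == "PA", ]), "2 groups")
  # normality reported but NA below n = 8
  expect_true(all(is.na(c7$normality$k2)))
  big <- generate_group_table(tibble::tibble(group = c("A", "B"),
                                             timepoint = 7, location = 0,
                                             scale = 1),
                              n_per_cell = 12, seed = 3)
  expect_true(all(is.finite(compare_groups(big)$normality$k2)))
})
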
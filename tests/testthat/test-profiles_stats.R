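test_that("features annotate to the nearest panel mass within the ppm bound", {
  fm <- feature_matrix(c(885.5512, 885.5600, 746.5130),
                       rbind(c(1, 1, 1)), data.frame(row = 0L, col = 0L))
  ann <- annotate_features(fm, max_ppm = 9)
  expect_equal(ann$species[1], "PI 38:4")
  expect_equal(ann$ppm_error[1], (885.5512 - 885.549853) / 885.549853 * 1e6,
               tolerance = 1e-2)
  # ~11.4 ppm away from every panel entry: flagged, not dropped
  expect_false(ann$accepted[2])
  expect_true(is.na(ann$species[2]))
  # the plasmalogen assignment records its suppressed alkyl-ether isobar
  expect_equal(ann$species[3], "PE P 38:6")
  expect_equal(ann$isobar_alternative[3], "PE O 38:7")
})

test_that("class percentages are the within-class intensity shares", {
  fm <- feature_matrix(c(766.5392, 744.5549),
                       rbind(c(30, 70), c(60, 140)),
                       data.frame(row = c(0L, 0L), col = c(0L, 1L)))
  ann <- annotate_features(fm)
  cp <- class_percentages(fm, ann)
  expect_equal(cp$percent[cp$species == "PE 38:4"], 30)
  expect_equal(cp$percent[cp$species == "PE 36:1"], 70)
  # single-species class reports 100
  one <- feature_matrix(885.5499, rbind(5), data.frame(row = 0L, col = 0L))
  cp1 <- class_percentages(one, annotate_features(one))
  expect_equal(cp1$percent, 100)
  expect_error(class_percentages(fm, ann, integer(0)), "empty")
})

test_that("class percentages are scale invariant and pixel-weighting agrees at zero noise", {
  sec <- small_section("tumor", params = noise_free_params(),
                       rows = 16, cols = 16, seed = 31)
  fm <- preprocess_cube(sec$cube, threshold_fraction = 0)
  ann <- annotate_features(fm)
  cp <- class_percentages(fm, ann)
  fm2 <- feature_matrix(fm$mz_axis, fm$values * 1e3, fm$pixel_index,
                        grid_shape = fm$grid_shape)
  expect_equal(class_percentages(fm2, ann)$percent, cp$percent)
  # within one tissue type (identical pixels at zero noise) the
  # intensity-weighted percentages equal the mean of per-pixel percentages
  grid <- sec$truth$phantom$label_grid
  epi <- which(grid[cbind(fm$pixel_index$row + 1L,
                          fm$pixel_index$col + 1L)] == 1L)
  cp_epi <- class_percentages(fm, ann, epi)
  pe_feat <- ann$feature[ann$accepted & ann$lipid_class == "PE"]
  pe_sp <- ann$species[ann$accepted & ann$lipid_class == "PE"]
  per_pixel <- t(apply(fm$values[epi, pe_feat], 1,
                       function(v) v / sum(v) * 100))
  expect_equal(colMeans(per_pixel),
               setNames(cp_epi$percent[cp_epi$lipid_class == "PE"],
                        cp_epi$species[cp_epi$lipid_class == "PE"])[pe_sp],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("group aggregation uses sections as replicates", {
  mk <- function(v) data.frame(lipid_class = "PI", species = "PI 38:4",
                               percent = v, n_pixels = 10)
  agg <- aggregate_group(list(mk(10), mk(20), mk(30)))
  expect_equal(agg$mean, 20)
  expect_equal(agg$sem, 10 / sqrt(3), tolerance = 1e-9)
  expect_equal(agg$sem, 5.774, tolerance = 1e-4)
  expect_true(is.na(aggregate_group(list(mk(10)))$sem))
  expect_equal(aggregate_group(list(mk(15), mk(15)))$sem, 0)
})

test_that("percent change reproduces the published worked examples", {
  expect_identical(percent_change(70.7, 58.5), -17.3)
  expect_identical(percent_change(18.8, 16.1), -14.4)
  expect_identical(percent_change(5, 5), 0.0)
  expect_warning(pc <- percent_change(0, 5), "zero reference")
  expect_true(is.na(pc))
})

test_that("forward and reverse percent changes are reciprocal", {
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 5, 95); b <- runif(1, 5, 95)
    prod <- (1 + percent_change(a, b) / 100) * (1 + percent_change(b, a) / 100)
    # the one-decimal rounding of each change bounds the product error
    expect_equal(prod, 1, tolerance = 0.01)
  }
})

test_that("group comparisons run unpaired t-tests with tiered stars", {
  mk <- function(v) data.frame(lipid_class = "PI", species = "PI 38:4",
                               percent = v, n_pixels = 10)
  same <- lapply(c(1, 2, 3), mk)
  res <- compare_groups(same, same)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$stars, "ns")

  set.seed(5)
  a <- lapply(10 + rnorm(4, 0, 0.01), mk)
  b <- lapply(20 + rnorm(4, 0, 0.01), mk)
  res2 <- compare_groups(a, b, group_names = c("ctrl", "case"))
  expect_lte(res2$p_value, 0.001)
  expect_equal(res2$stars, "***")
  expect_gt(res2$percent_change, 0)
  expect_equal(res2$mean_ctrl, 10, tolerance = 0.01)

  # degenerate equal-variance case: zero spread in both groups, p = 1
  const <- lapply(c(7, 7, 7), mk)
  res3 <- compare_groups(const, const)
  expect_equal(res3$p_value, 1)

  expect_error(compare_groups(list(mk(1)), same), ">= 2 sections")
})

test_that("significance stars follow the p-value tiers", {
  expect_equal(as.character(significance_stars(c(0.2, 0.05, 0.01, 0.001, 1e-6))),
               c("ns", "*", "**", "***", "***"))
})

test_that("multiple-testing correction is off by default but available", {
  mk <- function(sp, v) data.frame(lipid_class = "PI", species = sp,
                                   percent = v, n_pixels = 10)
  mk2 <- function(v1, v2) rbind(mk("PI 38:4", v1), mk("PI 34:1", v2))
  set.seed(6)
  a <- lapply(1:4, function(i) mk2(10 + rnorm(1), 50 + rnorm(1)))
  b <- lapply(1:4, function(i) mk2(12 + rnorm(1), 50 + rnorm(1)))
  raw <- compare_groups(a, b)
  bh <- compare_groups(a, b, p_adjust = "BH")
  expect_true(all(bh$p_value >= raw$p_value))
})
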
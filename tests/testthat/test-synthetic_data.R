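test_that("phantom layouts are deterministic and well formed", {
  a <- make_phantom(64, 64, "banded")
  b <- make_phantom(64, 64, "banded")
  expect_identical(a$label_grid, b$label_grid)
  counts <- table(factor(a$label_grid, levels = 0:3))
  expect_true(all(counts[c("1", "2", "3")] > 0))
  non_bg <- sum(counts[c("1", "2", "3")])
  expect_true(all(counts[c("1", "2", "3")] >= 0.10 * non_bg))
  expect_error(make_phantom(8, 64), "at least 16x16")

  nested <- make_phantom(48, 48, "nested")
  expect_setequal(unique(as.integer(nested$label_grid)), 0:3)

  rt <- make_phantom(20, 20, "from_mask", mask = a$label_grid[1:20, 1:20])
  expect_identical(rt$label_grid, a$label_grid[1:20, 1:20])
})

test_that("group profiles reproduce the published epithelial percentages", {
  expect_equal(default_group_profiles("tumor")$epithelium$classes$PI[["PI 38:4"]],
               67.3)
  expect_equal(default_group_profiles("non_tumor")$epithelium$classes$PI[["PI 38:4"]],
               41.5)
  expect_equal(default_group_profiles("non_tumor")$epithelium$classes$SM[["SM d34:1"]],
               70.7)
  expect_equal(default_group_profiles("tumor")$epithelium$classes$SM[["SM d34:1"]],
               58.5)
  expect_equal(default_group_profiles("tumor")$epithelium$classes$PE[["PE 38:4"]],
               27.7)
  expect_equal(default_group_profiles("non_tumor")$epithelium$classes$PE[["PE 38:4"]],
               14.5)
  expect_error(default_group_profiles("asthma"), "unknown group")
})

test_that("every class of every profile sums to 100", {
  for (g in study_groups()) {
    profs <- default_group_profiles(g)
    for (region in names(profs)) {
      sums <- vapply(profs[[region]]$classes, sum, numeric(1))
      expect_true(all(abs(sums - 100) < 1e-6),
                  info = paste(g, region))
      expect_true(all(unlist(profs[[region]]$classes) >= 0))
    }
  }
})

test_that("control stroma carries >= 2-fold arachidonic-acid species and depleted DHA", {
  profs <- default_group_profiles("control")
  epi <- profs$epithelium$classes
  for (stroma in c("cellular_stroma", "fibrous_stroma")) {
    st <- profs[[stroma]]$classes
    expect_gte(st$PI[["PI 38:4"]] / epi$PI[["PI 38:4"]], 2)
    expect_gte(st$PE[["PE 38:4"]] / epi$PE[["PE 38:4"]], 2)
    for (sp in c("PE 38:6", "PE 40:6", "PS 40:6")) {
      cls <- sub(" .*", "", sp)
      drop <- 1 - st[[cls]][[sp]] / epi[[cls]][[sp]]
      expect_true(drop >= 0.30 && drop <= 0.90, info = sp)
    }
  }
})

test_that("noise-free sampling recovers the profile exactly", {
  profile <- default_group_profiles("tumor")$epithelium
  set.seed(1)
  s <- sample_pixel_spectrum(profile, c(0L, 0L), params = noise_free_params())
  panel <- default_panel()
  lab <- panel$species[match(round(s$mz, 6), round(panel$mz_theoretical, 6))]
  pi_int <- s$intensity[lab %in% names(profile$classes$PI)]
  pct <- pi_int / sum(pi_int) * 100
  expect_equal(unname(pct[lab[lab %in% names(profile$classes$PI)] == "PI 38:4"]),
               67.3, tolerance = 1e-9)
})

test_that("sampling is reproducible and unbiased at default noise", {
  profile <- default_group_profiles("control")$epithelium
  set.seed(42)
  a <- sample_pixel_spectrum(profile, c(0L, 0L))
  set.seed(42)
  b <- sample_pixel_spectrum(profile, c(0L, 0L))
  expect_identical(a, b)

  # Monte-Carlo: 500 pixels, mean recovered PI 38:4 within 1 point
  set.seed(7)
  panel <- default_panel()
  pi_names <- names(profile$classes$PI)
  rec <- replicate(500, {
    s <- sample_pixel_spectrum(profile, c(0L, 0L))
    idx <- vapply(panel$mz_theoretical[match(pi_names, panel$species)],
                  function(m) which.min(abs(s$mz - m)), integer(1))
    v <- s$intensity[idx]
    v[which(pi_names == "PI 38:4")] / sum(v) * 100
  })
  expect_lt(abs(mean(rec) - profile$classes$PI[["PI 38:4"]]), 1)
})

test_that("simulate_section books one spectrum per tissue pixel and is seeded", {
  ph <- make_phantom(32, 32, "banded")
  profs <- default_group_profiles("control")
  sec1 <- simulate_section(ph, profs, seed = 9)
  expect_equal(length(sec1$cube$spectra), sum(ph$label_grid > 0))
  sec2 <- simulate_section(ph, profs, seed = 9)
  expect_identical(sec1$cube, sec2$cube)

  zero <- simulate_section(ph, profs, params = noise_free_params(), seed = 9)
  panel <- default_panel()
  for (s in zero$cube$spectra[c(1, 50)]) {
    ppm <- vapply(s$mz, function(m) {
      min(abs(m - panel$mz_theoretical) / panel$mz_theoretical * 1e6)
    }, numeric(1))
    expect_true(all(ppm < 1e-6))
  }

  expect_error(simulate_section(ph, profs["epithelium"], seed = 1),
               "no profile")
})

test_that("cohorts follow the study design and derive seeds deterministically", {
  secs <- simulate_cohort(rows = 16, cols = 16,
                          params = noise_free_params(), subject_sd = 0,
                          seed = 3)
  groups <- vapply(secs, `[[`, character(1), "group")
  expect_equal(as.integer(table(groups)[c("tumor", "non_tumor", "copd",
                                          "smoker", "control")]),
               c(5L, 5L, 4L, 5L, 4L))
  secs2 <- simulate_cohort(rows = 16, cols = 16,
                           params = noise_free_params(), subject_sd = 0,
                           seed = 3)
  expect_identical(secs, secs2)
  # subject_sd = 0: all sections of a group share the group profile
  tum <- Filter(function(s) s$group == "tumor", secs)
  expect_identical(tum[[1]]$truth$profiles, tum[[2]]$truth$profiles)
  expect_error(simulate_cohort(groups = c(control = 0)), "positive")
})

test_that("ground-truth bundles serialize to TSV + JSON", {
  sec <- small_section(rows = 16, cols = 16, seed = 2)
  dir <- file.path(withr::local_tempdir(), "truth")
  write_ground_truth(sec$truth, dir)
  grid <- read_label_mask(file.path(dir, "label_grid.tsv"))
  expect_identical(grid, sec$truth$phantom$label_grid)
  js <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(js$profiles$epithelium$classes$PI[["PI 38:4"]], 30.0)
})
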
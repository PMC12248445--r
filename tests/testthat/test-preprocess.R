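test_that("TIC normalization equalizes per-pixel sums and keeps scale", {
  cube <- tiny_cube()  # TICs 10 and 100
  norm <- tic_normalize(cube)
  sums <- vapply(norm$spectra, function(s) sum(s$intensity), numeric(1))
  expect_equal(sums[1], sums[2])
  expect_equal(mean(sums), mean(c(10, 100)))  # global scale preserved

  one <- msi_datacube(list(pixel_spectrum(c(600, 700), c(3, 7), c(0L, 0L))),
                      c(1L, 1L))
  norm1 <- tic_normalize(one)
  expect_equal(norm1$spectra[[1]]$intensity, c(3, 7))
})

test_that("zero-TIC pixels are dropped with a counted warning", {
  spectra <- list(pixel_spectrum(600, 5, c(0L, 0L)),
                  pixel_spectrum(600, 0, c(0L, 1L)))
  cube <- msi_datacube(spectra, c(1L, 2L))
  expect_warning(norm <- tic_normalize(cube), "1 zero-TIC")
  expect_equal(length(norm$spectra), 1)
  expect_equal(attr(norm, "dropped_pixels"), 1)
})

test_that("alignment groups peaks by ppm distance to the running centroid", {
  # 885.5499 vs 885.5520 are ~2.4 ppm apart
  cube <- msi_datacube(list(pixel_spectrum(885.5499, 1, c(0L, 0L)),
                            pixel_spectrum(885.5520, 1, c(0L, 1L))),
                       c(1L, 2L))
  expect_equal(length(align_peaks(cube, tolerance_ppm = 5)$mz_axis), 1)
  expect_equal(length(align_peaks(cube, tolerance_ppm = 1)$mz_axis), 2)
  expect_error(align_peaks(cube, tolerance_ppm = 0), "tolerance")
})

test_that("a jitter-free cube aligns to exactly one feature per species", {
  sec <- small_section(params = noise_free_params(), rows = 16, cols = 16,
                       seed = 4)
  fm <- align_peaks(sec$cube)
  expect_equal(length(fm$mz_axis), nrow(default_panel()))
  expect_equal(sort(fm$mz_axis), sort(default_panel()$mz_theoretical),
               tolerance = 1e-12)
})

test_that("alignment is invariant to pixel order and monotone in tolerance", {
  sec <- small_section(rows = 16, cols = 16, seed = 8)
  cube <- sec$cube
  perm <- rev(seq_along(cube$spectra))
  cube_perm <- msi_datacube(cube$spectra[perm], cube$grid_shape)
  expect_equal(align_peaks(cube)$mz_axis, align_peaks(cube_perm)$mz_axis)

  counts <- vapply(c(1, 2, 5, 10, 20), function(tol) {
    length(align_peaks(cube, tolerance_ppm = tol)$mz_axis)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the low-intensity filter drops features below the 0.5% rule", {
  fm <- feature_matrix(c(600, 700, 800), rbind(c(1000, 6, 4)),
                       data.frame(row = 0L, col = 0L))
  kept <- filter_low_intensity(fm, 0.005)
  expect_equal(kept$mz_axis, c(600, 700))  # threshold = 5 drops the 4

  expect_equal(filter_low_intensity(fm, 0)$mz_axis, fm$mz_axis)

  flat <- feature_matrix(c(600, 700), rbind(c(5, 5)),
                         data.frame(row = 0L, col = 0L))
  expect_equal(length(filter_low_intensity(flat, 0.005)$mz_axis), 2)
  empty <- feature_matrix(numeric(0), matrix(0, 1, 0),
                          data.frame(row = 0L, col = 0L))
  expect_error(filter_low_intensity(empty), "empty")
})

test_that("the filter is monotone: retained sets shrink with the threshold", {
  sec <- small_section(rows = 16, cols = 16, seed = 10)
  fm <- align_peaks(tic_normalize(sec$cube))
  prev <- fm$mz_axis
  for (thr in c(0.001, 0.005, 0.02, 0.1)) {
    cur <- filter_low_intensity(fm, thr)$mz_axis
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("normalize and align commute on jitter-free data", {
  sec <- small_section(params = acquisition_params(
    ppm_jitter_sd = 0, tic_lognormal_sd = 0.3,
    pixel_dirichlet_concentration = 200,
    noise_peak_rate = 0), rows = 16, cols = 16, seed = 11)
  a <- align_peaks(tic_normalize(sec$cube))
  b_raw <- align_peaks(sec$cube)
  # row-normalize the aligned matrix afterwards
  sums <- rowSums(b_raw$values)
  b_vals <- sweep(b_raw$values, 1, sums, "/") * mean(sums)
  expect_equal(a$mz_axis, b_raw$mz_axis, tolerance = 1e-12)
  expect_equal(a$values, b_vals, tolerance = 1e-9)
})
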
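test_that("pixel spectra and datacubes validate their invariants", {
  expect_error(pixel_spectrum(c(1, 2), c(1), c(0, 0)), "lengths differ")
  expect_error(pixel_spectrum(c(2, 1), c(1, 1), c(0, 0)), "ascending")
  expect_error(pixel_spectrum(c(1, 2), c(1, -1), c(0, 0)), "non-negative")
  s <- pixel_spectrum(600, 1, c(0L, 0L))
  expect_error(msi_datacube(list(s, s), c(2L, 2L)), "collision")
  expect_error(msi_datacube(list(pixel_spectrum(600, 1, c(5L, 0L))),
                            c(2L, 2L)), "outside grid")
})

test_that("imzML round-trip is lossless for m/z and coordinates", {
  sec <- small_section(rows = 16, cols = 16, seed = 5)
  path <- file.path(withr::local_tempdir(), "cube.imzML")
  write_imzml(sec$cube, path)
  back <- read_imzml(path)
  expect_equal(length(back$spectra), length(sec$cube$spectra))
  expect_equal(back$grid_shape, sec$cube$grid_shape)
  expect_equal(back$pixel_size, sec$cube$pixel_size)
  for (i in c(1, 7, length(back$spectra))) {
    expect_identical(back$spectra[[i]]$coord, sec$cube$spectra[[i]]$coord)
    # m/z stored as 64-bit floats: exact
    expect_equal(back$spectra[[i]]$mz, sec$cube$spectra[[i]]$mz,
                 tolerance = 1e-9 / 600)
    # intensities stored as 32-bit floats on disk
    expect_equal(back$spectra[[i]]$intensity, sec$cube$spectra[[i]]$intensity,
                 tolerance = 1e-6)
  }
})

test_that("coordinate convention maps memory (0,0) to file (1,1)", {
  cube <- msi_datacube(list(pixel_spectrum(c(600, 700), c(1, 2), c(0L, 0L))),
                       c(1L, 1L))
  path <- file.path(withr::local_tempdir(), "one.imzML")
  write_imzml(cube, path)
  txt <- readChar(path, file.size(path))
  expect_match(txt, 'IMS:1000050" name="position x" value="1"')
  expect_match(txt, 'IMS:1000051" name="position y" value="1"')
  back <- read_imzml(path)
  expect_identical(back$spectra[[1]]$coord, c(0L, 0L))
})

test_that("empty cubes and continuous-mode files are rejected", {
  expect_error(write_imzml(msi_datacube(list(), c(2L, 2L)),
                           file.path(tempdir(), "x.imzML")), "empty")
  sec <- small_section(rows = 16, cols = 16, seed = 6)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cont.imzML")
  write_imzml(sec$cube, path)
  txt <- readChar(path, file.size(path))
  txt <- sub('accession="IMS:1000031" name="processed"',
             'accession="IMS:1000030" name="continuous"', txt)
  writeLines(txt, path, sep = "")
  expect_error(read_imzml(path), "continuous")
})

test_that("the written imzML is readable by an independent parser", {
  sec <- small_section(rows = 16, cols = 16, seed = 7)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cube.imzML")
  write_imzml(sec$cube, path)
  script <- file.path(dir, "parse.py")
  writeLines(c(
    "import sys, json",
    "from pyimzml.ImzMLParser import ImzMLParser",
    "p = ImzMLParser(sys.argv[1])",
    "mz, inten = p.getspectrum(0)",
    "json.dump({'n': len(p.coordinates), 'first_xy': list(p.coordinates[0][:2]),",
    "           'mz0': float(mz[0])}, sys.stdout)"), script)
  out <- suppressWarnings(system2("python", c(script, path), stdout = TRUE))
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(parsed$n, length(sec$cube$spectra))
  s1 <- sec$cube$spectra[[1]]
  expect_equal(parsed$first_xy, c(s1$coord[2] + 1L, s1$coord[1] + 1L))
  expect_equal(parsed$mz0, s1$mz[1], tolerance = 1e-9)
})

test_that("label masks round-trip through TSV and PNG", {
  ph <- make_phantom(24, 24, "banded")
  dir <- withr::local_tempdir()
  for (ext in c("mask.tsv", "mask.png")) {
    path <- file.path(dir, ext)
    write_label_mask(ph$label_grid, path)
    expect_identical(read_label_mask(path), ph$label_grid)
  }
})

test_that("degenerate masks are flagged", {
  dir <- withr::local_tempdir()
  p_bad <- file.path(dir, "bad.tsv")
  utils::write.table(matrix(c(1.5, 2, 0, 1), 2), p_bad, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  expect_error(read_label_mask(p_bad), "non-integer")
  p_bg <- file.path(dir, "bg.tsv")
  write_label_mask(matrix(0L, 4, 4), p_bg)
  expect_warning(read_label_mask(p_bg), "all background")
})
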
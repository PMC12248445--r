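# shared fixture builders; everything is generated in code at test time

# a small banded section for one study group
small_section <- function(group = "control", params = acquisition_params(),
                          rows = 32, cols = 32, seed = 1) {
  ph <- make_phantom(rows, cols, "banded")
  simulate_section(ph, default_group_profiles(group), params = params,
                   seed = seed)
}

# a two-region phantom with species exclusive to each region, useful for
# clean separability checks
two_region_fixture <- function(rows = 20, cols = 20) {
  mask <- matrix(1L, rows, cols)
  mask[, (cols %/% 2 + 1):cols] <- 2L
  phantom <- make_phantom(rows, cols, "from_mask", mask = mask)
  profiles <- list(
    epithelium = region_profile(
      list(PI = c("PI 38:4" = 60, "PI 34:1" = 40),
           PE = c("PE 38:6" = 100)),
      class_weights = c(PI = 0.6, PE = 0.4)),
    cellular_stroma = region_profile(
      list(PI = c("PI 36:2" = 50, "PI 32:0" = 50),
           PE = c("PE 36:1" = 100)),
      class_weights = c(PI = 0.4, PE = 0.6))
  )
  list(phantom = phantom, profiles = profiles)
}

# a tiny hand-built cube: two pixels, three shared peak positions
tiny_cube <- function() {
  s1 <- pixel_spectrum(c(600.0, 700.0, 800.0), c(1, 2, 7), c(0L, 0L))
  s2 <- pixel_spectrum(c(600.0, 700.0, 800.0), c(10, 20, 70), c(0L, 1L))
  msi_datacube(list(s1, s2), c(1L, 2L))
}
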
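#' @title Ion images and segment maps
#' @description Renders per-feature intensity rasters (ion images) with
#'   linear or quantile scaling, background pixels transparent.
#' @name viz
NULL

#' Render an ion image for one feature
#'
#' Maps the intensity of the feature closest to `mz` (within
#' `tolerance_ppm`) onto the pixel grid and colors it with a continuous
#' palette. Background (spectrum-free) pixels are transparent. Quantile
#' scaling clips hotspots at an upper percentile before normalizing.
#'
#' @param fm An [feature_matrix()] with a known grid shape.
#' @param mz Target feature m/z (Da).
#' @param tolerance_ppm Maximum distance to the nearest feature (default 9).
#' @param scale `"linear"` or `"quantile"`.
#' @param upper_quantile Clipping percentile for quantile scaling
#'   (default 0.99).
#' @param colormap Palette name passed to [grDevices::hcl.colors()]
#'   (default "viridis").
#' @return rows x cols x 4 RGBA array (class `ion_image`); attribute
#'   `"feature_mz"` records the feature rendered.
#' @export
render_ion_image <- function(fm, mz, tolerance_ppm = 9,
                             scale = c("linear", "quantile"),
                             upper_quantile = 0.99,
                             colormap = "viridis") {
  scale <- match.arg(scale)
  if (is.null(fm$grid_shape)) stop("feature matrix has no grid shape",
                                   call. = FALSE)
  ppm <- abs(fm$mz_axis - mz) / mz * 1e6
  j <- which.min(ppm)
  if (ppm[j] > tolerance_ppm) {
    stop(sprintf("no feature within %g ppm of m/z %.4f", tolerance_ppm, mz),
         call. = FALSE)
  }
  v <- fm$values[, j]
  if (scale == "quantile") {
    cap <- stats::quantile(v, upper_quantile)
    v <- pmin(v, cap)
  }
  rng <- range(v)
  z <- if (diff(rng) == 0) rep(0.5, length(v)) else
    (v - rng[1]) / diff(rng)
  pal <- grDevices::hcl.colors(256, colormap)
  cols <- grDevices::col2rgb(pal[pmin(255, floor(z * 255)) + 1L]) / 255
  img <- array(0, c(fm$grid_shape[1], fm$grid_shape[2], 4))
  idx <- cbind(fm$pixel_index$row + 1L, fm$pixel_index$col + 1L)
  for (ch in 1:3) {
    layer <- matrix(0, fm$grid_shape[1], fm$grid_shape[2])
    layer[idx] <- cols[ch, ]
    img[, , ch] <- layer
  }
  alpha <- matrix(0, fm$grid_shape[1], fm$grid_shape[2])
  alpha[idx] <- 1
  img[, , 4] <- alpha
  structure(img, class = c("ion_image", class(img)),
            feature_mz = fm$mz_axis[j])
}

#' Write an ion image to PNG
#'
#' @param img An `ion_image` array from [render_ion_image()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_ion_image <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}
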
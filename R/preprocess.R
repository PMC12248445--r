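#' @title Spectrum preprocessing
#' @description The processing chain applied to centroided pixel spectra,
#'   in order: total-ion-current normalization, ppm-window peak alignment
#'   into a feature matrix, and low-intensity feature filtering against the
#'   dataset mean spectrum.
#' @name preprocess
NULL

#' Total-ion-current normalization
#'
#' Divides each spectrum by its TIC and rescales by the mean TIC over
#' pixels, so every retained pixel has the same post-normalization
#' intensity sum while the global intensity scale is preserved. Pixels
#' with zero TIC are dropped with a warning reporting the count.
#'
#' @param cube An [msi_datacube()].
#' @return Normalized `msi_datacube`; attribute `"dropped_pixels"` carries
#'   the number of zero-TIC pixels removed.
#' @export
tic_normalize <- function(cube) {
  tics <- vapply(cube$spectra, function(s) sum(s$intensity), numeric(1))
  keep <- tics > 0
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    warning(sprintf("dropped %d zero-TIC pixel(s)", n_drop))
  }
  spectra <- cube$spectra[keep]
  mean_tic <- mean(tics[keep])
  spectra <- Map(function(s, tic) {
    s$intensity <- s$intensity / tic * mean_tic
    s
  }, spectra, tics[keep])
  out <- msi_datacube(spectra, cube$grid_shape,
                      pixel_size = cube$pixel_size,
                      polarity = cube$polarity)
  attr(out, "dropped_pixels") <- n_drop
  attr(out, "normalized") <- TRUE
  out
}

#' Construct a feature matrix
#'
#' Aligned features (columns) by pixels (rows). Built by [align_peaks()];
#' the constructor is exported for programmatic assembly in tests.
#'
#' @param mz_axis Ascending numeric vector of feature m/z values.
#' @param values pixels x features numeric matrix of intensities.
#' @param pixel_index data.frame with 0-based `row`, `col` per pixel.
#' @param normalized Logical, whether intensities are TIC-normalized.
#' @param grid_shape Integer `c(rows, cols)` of the source grid.
#' @return Object of class `msi_feature_matrix`.
#' @export
feature_matrix <- function(mz_axis, values, pixel_index, normalized = FALSE,
                           grid_shape = NULL) {
  values <- as.matrix(values)
  if (length(mz_axis) != ncol(values)) {
    stop("mz_axis length must equal feature count", call. = FALSE)
  }
  if (nrow(pixel_index) != nrow(values)) {
    stop("pixel_index must have one row per pixel", call. = FALSE)
  }
  if (any(values < 0)) stop("feature intensities must be >= 0",
                            call. = FALSE)
  structure(list(mz_axis = as.numeric(mz_axis), values = values,
                 pixel_index = pixel_index, normalized = normalized,
                 grid_shape = grid_shape),
            class = "msi_feature_matrix")
}

#' @export
print.msi_feature_matrix <- function(x, ...) {
  cat(sprintf("<msi_feature_matrix> %d pixels x %d features, m/z %.4f-%.4f%s\n",
              nrow(x$values), ncol(x$values),
              min(x$mz_axis), max(x$mz_axis),
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Align peaks across pixels into features
#'
#' Greedy 1-D clustering on the pooled, sorted m/z values of all pixels:
#' scanning upward, a new feature opens whenever the next peak lies more
#' than `tolerance_ppm` from the running intensity-weighted centroid of
#' the current feature. The feature m/z is the intensity-weighted mean of
#' its member peaks; each pixel contributes at most one peak per feature
#' (the most intense wins, ties broken toward lower m/z).
#'
#' @param cube An [msi_datacube()] of centroided spectra.
#' @param tolerance_ppm Alignment window in ppm (default 5).
#' @return An [feature_matrix()] ordered by ascending feature m/z.
#' @export
align_peaks <- function(cube, tolerance_ppm = 5) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0", call. = FALSE)
  n_pix <- length(cube$spectra)
  if (n_pix == 0) stop("empty datacube", call. = FALSE)
  pix <- rep.int(seq_len(n_pix),
                 vapply(cube$spectra, function(s) length(s$mz), integer(1)))
  mz <- unlist(lapply(cube$spectra, `[[`, "mz"), use.names = FALSE)
  inten <- unlist(lapply(cube$spectra, `[[`, "intensity"), use.names = FALSE)
  o <- order(mz)
  mz <- mz[o]; inten <- inten[o]; pix <- pix[o]

  n <- length(mz)
  feat <- integer(n)
  f <- 0L
  sum_w <- 0; sum_wm <- 0
  for (i in seq_len(n)) {
    open_new <- f == 0L
    if (!open_new) {
      centroid <- sum_wm / sum_w
      open_new <- (mz[i] - centroid) / centroid * 1e6 > tolerance_ppm
    }
    if (open_new) {
      f <- f + 1L
      sum_w <- 0; sum_wm <- 0
    }
    feat[i] <- f
    w <- if (inten[i] > 0) inten[i] else .Machine$double.eps
    sum_w <- sum_w + w
    sum_wm <- sum_wm + w * mz[i]
  }

  w <- ifelse(inten > 0, inten, .Machine$double.eps)
  mz_axis <- as.numeric(tapply(w * mz, feat, sum) / tapply(w, feat, sum))

  values <- matrix(0, n_pix, f)
  # most intense peak per (pixel, feature); sorted order makes the
  # lower-m/z member win intensity ties
  ord <- order(pix, feat, -inten, mz)
  first <- !duplicated(cbind(pix, feat)[ord, , drop = FALSE])
  sel <- ord[first]
  values[cbind(pix[sel], feat[sel])] <- inten[sel]

  coords <- .cube_coords(cube)
  pixel_index <- data.frame(row = coords[, 1], col = coords[, 2])
  feature_matrix(mz_axis, values, pixel_index,
                 normalized = isTRUE(attr(cube, "normalized")),
                 grid_shape = cube$grid_shape)
}

#' Filter low-intensity features
#'
#' Computes the dataset mean spectrum over pixels and drops every feature
#' whose mean intensity falls below `threshold_fraction` of the strongest
#' mean-spectrum feature. Operating on the aggregate spectrum (rather than
#' per pixel) preserves genuine low-abundance species within individual
#' pixels, keeping class percentages comparable across pixels.
#'
#' @param fm An [feature_matrix()].
#' @param threshold_fraction Fraction of the maximum mean-spectrum
#'   intensity below which a feature is dropped (default 0.005, i.e. the
#'   0.5 % rule).
#' @return Filtered `msi_feature_matrix`; attributes `"retained"` and
#'   `"dropped"` report feature counts.
#' @export
filter_low_intensity <- function(fm, threshold_fraction = 0.005) {
  if (ncol(fm$values) == 0) stop("empty feature matrix", call. = FALSE)
  mean_spec <- colMeans(fm$values)
  keep <- mean_spec >= threshold_fraction * max(mean_spec)
  out <- feature_matrix(fm$mz_axis[keep], fm$values[, keep, drop = FALSE],
                        fm$pixel_index, normalized = fm$normalized,
                        grid_shape = fm$grid_shape)
  attr(out, "retained") <- sum(keep)
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Run the full preprocessing chain
#'
#' Normalize, align, filter -- in that order.
#'
#' @param cube An [msi_datacube()].
#' @param tolerance_ppm Alignment window (default 5 ppm).
#' @param threshold_fraction Low-intensity cutoff (default 0.005).
#' @return A filtered, normalized [feature_matrix()].
#' @export
preprocess_cube <- function(cube, tolerance_ppm = 5,
                            threshold_fraction = 0.005) {
  filter_low_intensity(
    align_peaks(tic_normalize(cube), tolerance_ppm = tolerance_ppm),
    threshold_fraction = threshold_fraction)
}

#' Export a feature matrix as TSV
#'
#' Writes a `features x pixels` intensity table plus a feature table
#' (feature m/z, mean intensity).
#'
#' @param fm An [feature_matrix()].
#' @param path Base path; `_matrix.tsv` and `_features.tsv` are appended.
#' @return Invisibly, the two paths written.
#' @export
write_feature_matrix <- function(fm, path) {
  m_path <- paste0(path, "_matrix.tsv")
  f_path <- paste0(path, "_features.tsv")
  tab <- t(fm$values)
  colnames(tab) <- paste0("px_", fm$pixel_index$row, "_", fm$pixel_index$col)
  utils::write.table(
    data.frame(mz = fm$mz_axis, tab, check.names = FALSE),
    m_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(mz = fm$mz_axis, mean_intensity = colMeans(fm$values)),
    f_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(m_path, f_path))
}
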
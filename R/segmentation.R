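#' @title Hierarchical divisive rank-based segmentation
#' @description Partitions pixels into lipid segments by divisive bisecting
#'   2-means on within-pixel rank-transformed feature vectors, selecting at
#'   each step the segment with the largest heterogeneity (sum of squared
#'   rank deviations from the segment mean). The rank transform makes the
#'   segmentation invariant to any positive rescaling of intensities.
#' @name segmentation
NULL

# within-pixel rank transform: each pixel's feature vector replaced by its
# ranks (ties averaged); this is the robustness device of the divisive
# rank-based scheme
.rank_transform <- function(values) {
  t(apply(values, 1, rank))
}

.heterogeneity <- function(x) {
  if (nrow(x) < 2) return(0)
  sum(sweep(x, 2, colMeans(x))^2)
}

# deterministic 2-means: centers initialized one standard deviation apart
# along the first principal component of the segment (outlier-robust, no
# randomness), then Lloyd iterations; returns NULL when the segment has no
# spread or the bisection degenerates
.two_means <- function(x, max_iter = 50) {
  n <- nrow(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = 1)
  proj <- xc %*% sv$v[, 1]
  if (all(proj == 0)) return(NULL)  # no spread to split
  s <- stats::sd(proj)
  c1 <- ctr + s * sv$v[, 1]
  c2 <- ctr - s * sv$v[, 1]
  assign <- rep(1L, n)
  for (iter in seq_len(max_iter)) {
    da <- rowSums(sweep(x, 2, c1)^2)
    db <- rowSums(sweep(x, 2, c2)^2)
    new_assign <- ifelse(db < da, 2L, 1L)  # ties stay with cluster 1
    if (all(new_assign == assign) && iter > 1) break
    assign <- new_assign
    if (all(assign == 1L) || all(assign == 2L)) return(NULL)
    c1 <- colMeans(x[assign == 1L, , drop = FALSE])
    c2 <- colMeans(x[assign == 2L, , drop = FALSE])
  }
  assign
}

#' Segment pixels by hierarchical divisive rank-based clustering
#'
#' Starts from a single segment holding every pixel and repeatedly bisects
#' the segment with the largest heterogeneity until `k` segments exist, no
#' splittable segment remains (minimum size, zero heterogeneity, or a
#' degenerate bisection), at which point fewer segments are returned with
#' a warning. The procedure is deterministic: each bisection is a 2-means
#' initialized along the segment's first principal component.
#'
#' @param fm An [feature_matrix()], normalized and filtered.
#' @param k Target number of segments (>= 1).
#' @param min_segment_size Segments smaller than twice this are not split
#'   (default 10).
#' @return Object of class `segmentation_result` with `labels` (integer
#'   per pixel), `n_segments`, `segment_means` (segments x features, on
#'   the original intensity scale), `heterogeneity` per segment and
#'   `split_tree` (list of `(parent, children, heterogeneity)` records).
#' @export
hdrca_segment <- function(fm, k, min_segment_size = 10) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- nrow(fm$values)
  if (k > n) stop("k exceeds number of pixels", call. = FALSE)
  rx <- .rank_transform(fm$values)
  labels <- rep(1L, n)
  het <- c(.heterogeneity(rx))
  tree <- list()
  next_id <- 1L
  while (length(unique(labels)) < k) {
    ids <- sort(unique(labels))
    seg_het <- het[ids]
    sizes <- tabulate(labels, nbins = max(ids))[ids]
    splittable <- seg_het > 1e-12 & sizes >= 2 * min_segment_size
    if (!any(splittable)) {
      warning(sprintf(
        "requested k = %d but only %d segment(s) could be formed",
        k, length(ids)))
      break
    }
    target <- ids[splittable][which.max(seg_het[splittable])]
    members <- which(labels == target)
    assign <- .two_means(rx[members, , drop = FALSE])
    if (is.null(assign) ||
        min(tabulate(assign, 2)) < min_segment_size) {
      het[target] <- 0  # mark unsplittable, try the next candidate
      next
    }
    id_a <- next_id + 1L; id_b <- next_id + 2L; next_id <- next_id + 2L
    labels[members[assign == 1L]] <- id_a
    labels[members[assign == 2L]] <- id_b
    het[id_a] <- .heterogeneity(rx[labels == id_a, , drop = FALSE])
    het[id_b] <- .heterogeneity(rx[labels == id_b, , drop = FALSE])
    tree[[length(tree) + 1]] <- list(parent = target,
                                     children = c(id_a, id_b),
                                     heterogeneity = unname(het[target]))
  }
  ids <- sort(unique(labels))
  relabel <- match(labels, ids)
  means <- t(vapply(ids, function(i) {
    colMeans(fm$values[labels == i, , drop = FALSE])
  }, numeric(ncol(fm$values))))
  final_het <- vapply(ids, function(i) {
    .heterogeneity(rx[labels == i, , drop = FALSE])
  }, numeric(1))
  structure(list(labels = relabel,
                 n_segments = length(ids),
                 segment_means = means,
                 heterogeneity = final_het,
                 split_tree = tree,
                 mz_axis = fm$mz_axis,
                 pixel_index = fm$pixel_index,
                 grid_shape = fm$grid_shape),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d segments over %d pixels (sizes: %s)\n",
              x$n_segments, length(x$labels),
              paste(tabulate(x$labels, x$n_segments), collapse = ", ")))
  invisible(x)
}

#' Total within-segment heterogeneity of a segmentation
#' @param result A `segmentation_result`.
#' @param fm The feature matrix it was computed from.
#' @return Sum over segments of squared rank-space deviations.
#' @export
total_heterogeneity <- function(result, fm) {
  rx <- .rank_transform(fm$values)
  sum(vapply(seq_len(result$n_segments), function(i) {
    .heterogeneity(rx[result$labels == i, , drop = FALSE])
  }, numeric(1)))
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Integer label vectors of equal length.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

#' Match segments to a tissue label mask
#'
#' Assigns every segment the tissue type it overlaps most (majority vote)
#' and reports per-segment purity and the overall adjusted Rand index
#' against the mask. This replaces the expert-pathologist confirmation
#' step available for real sections.
#'
#' @param result A `segmentation_result`.
#' @param phantom A [make_phantom()] phantom or an integer label matrix of
#'   the same grid shape.
#' @return List with `assignment` (data.frame segment, tissue, size,
#'   purity), `ari`, and `tissue_of_pixel` (character per pixel).
#' @export
match_segments_to_mask <- function(result, phantom) {
  grid <- if (inherits(phantom, "tissue_phantom")) phantom$label_grid
          else phantom
  if (!is.null(result$grid_shape) &&
      !all(dim(grid) == result$grid_shape)) {
    stop("mask dimensions do not match segmentation grid", call. = FALSE)
  }
  truth <- grid[cbind(result$pixel_index$row + 1L,
                      result$pixel_index$col + 1L)]
  lab_names <- names(.TISSUE_LABELS)
  assignment <- do.call(rbind, lapply(seq_len(result$n_segments), function(i) {
    members <- truth[result$labels == i]
    tab <- table(members)
    top <- as.integer(names(tab)[which.max(tab)])
    data.frame(segment = i,
               tissue = lab_names[match(top, .TISSUE_LABELS)],
               size = length(members),
               purity = max(tab) / length(members))
  }))
  tissue_of_pixel <- assignment$tissue[result$labels]
  list(assignment = assignment,
       ari = adjusted_rand_index(result$labels, truth),
       tissue_of_pixel = tissue_of_pixel)
}

#' Export segment labels as a mask
#'
#' @param result A `segmentation_result` with a known grid shape.
#' @param path Output TSV/PNG path (see [write_label_mask()]); background
#'   pixels get label 0.
#' @return Invisibly, `path`.
#' @export
write_segment_mask <- function(result, path) {
  grid <- matrix(0L, result$grid_shape[1], result$grid_shape[2])
  grid[cbind(result$pixel_index$row + 1L,
             result$pixel_index$col + 1L)] <- result$labels
  write_label_mask(grid, path)
}

#' Export the split tree as JSON
#' @param result A `segmentation_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_split_tree <- function(result, path) {
  jsonlite::write_json(result$split_tree, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
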
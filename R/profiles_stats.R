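#' @title Lipid-class percentage profiles and group statistics
#' @description Annotates aligned features against the theoretical panel by
#'   ppm mass matching, converts intensities into within-class species
#'   percentages (for a class X and species i:
#'   `Xi% = I_Xi / sum(I_X) * 100`), aggregates section-level profiles into
#'   group means with SEM, and compares groups with multiple unpaired
#'   t-tests.
#' @name profiles_stats
NULL

#' Annotate features by ppm mass matching
#'
#' Each feature is matched to the panel entry minimizing the absolute ppm
#' error `(observed - theoretical) / theoretical * 1e6` and accepted iff
#' that error is below `max_ppm` in magnitude. Unmatched features are
#' flagged unannotated, never dropped. Plasmalogen (PE P) assignments are
#' isobaric with alkyl-ether PE O carrying one more double bond; the
#' suppressed alternative is recorded in the `isobar_alternative` column.
#'
#' @param fm An [feature_matrix()].
#' @param panel Annotation panel (default [default_panel()]).
#' @param max_ppm Acceptance bound in ppm (default 9, the assignment
#'   accuracy limit; typical errors are below 3 ppm).
#' @return data.frame with one row per feature: `feature`, `mz_observed`,
#'   `species`, `lipid_class`, `mz_theoretical`, `ppm_error`, `accepted`,
#'   `isobar_alternative`.
#' @export
annotate_features <- function(fm, panel = default_panel(), max_ppm = 9) {
  if (nrow(panel) == 0) stop("empty panel", call. = FALSE)
  res <- lapply(seq_along(fm$mz_axis), function(i) {
    obs <- fm$mz_axis[i]
    ppm <- (obs - panel$mz_theoretical) / panel$mz_theoretical * 1e6
    j <- which.min(abs(ppm))
    ok <- abs(ppm[j]) < max_ppm
    data.frame(
      feature = i,
      mz_observed = obs,
      species = if (ok) panel$species[j] else NA_character_,
      lipid_class = if (ok) panel$lipid_class[j] else NA_character_,
      mz_theoretical = if (ok) panel$mz_theoretical[j] else NA_real_,
      ppm_error = if (ok) ppm[j] else NA_real_,
      accepted = ok,
      isobar_alternative = if (ok) panel$isobar_alternative[j]
                           else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Within-class species percentages over a pixel subset
#'
#' For every lipid class, sums each annotated species' intensity over the
#' selected pixels and divides by the class total (times 100). Multiple
#' features annotated to the same species are pooled. Classes with zero
#' total intensity report their species as missing (`NA`), not 0/0.
#'
#' @param fm An [feature_matrix()].
#' @param annotation Output of [annotate_features()].
#' @param pixels Integer vector of pixel row indices into `fm$values`
#'   (default all pixels).
#' @return data.frame `lipid_class`, `species`, `percent`, `n_pixels`.
#' @export
class_percentages <- function(fm, annotation, pixels = NULL) {
  if (is.null(pixels)) pixels <- seq_len(nrow(fm$values))
  if (length(pixels) == 0) stop("empty pixel subset", call. = FALSE)
  ann <- annotation[annotation$accepted, , drop = FALSE]
  if (nrow(ann) == 0) stop("no accepted annotations", call. = FALSE)
  sub <- fm$values[pixels, ann$feature, drop = FALSE]
  totals <- colSums(sub)
  by_species <- tapply(totals, list(ann$lipid_class, ann$species), sum)
  out <- do.call(rbind, lapply(sort(unique(ann$lipid_class)), function(cls) {
    sp <- ann$species[ann$lipid_class == cls]
    sp <- sort(unique(sp))
    vals <- vapply(sp, function(s) sum(totals[ann$species == s]), numeric(1))
    class_total <- sum(vals)
    pct <- if (class_total > 0) vals / class_total * 100 else
      rep(NA_real_, length(vals))
    data.frame(lipid_class = cls, species = sp, percent = pct,
               n_pixels = length(pixels), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate section-level profiles into group mean and SEM
#'
#' Sections (biological replicates) are the unit of replication: for each
#' species the section-level percentages are averaged and the SEM is
#' `sd / sqrt(n)` with `n` the number of sections, never the pixel count.
#' With a single section the SEM is reported missing.
#'
#' @param profiles List of data.frames from [class_percentages()], one per
#'   section.
#' @return data.frame `lipid_class`, `species`, `mean`, `sem`, `n_sections`.
#' @export
aggregate_group <- function(profiles) {
  stacked <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    p$section <- i
    p
  }))
  key <- paste(stacked$lipid_class, stacked$species, sep = "\r")
  out <- do.call(rbind, lapply(unique(key), function(k) {
    rows <- stacked[key == k, , drop = FALSE]
    x <- rows$percent[!is.na(rows$percent)]
    n <- length(x)
    data.frame(lipid_class = rows$lipid_class[1],
               species = rows$species[1],
               mean = if (n > 0) mean(x) else NA_real_,
               sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
               n_sections = n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$lipid_class, out$species), ]
}

#' Percent change between two group means
#'
#' `(mean_B - mean_A) / mean_A * 100`, reported to one decimal place.
#'
#' @param mean_A Reference group mean (> 0).
#' @param mean_B Comparison group mean.
#' @return Signed percent change rounded to one decimal; `NA` with a
#'   warning when `mean_A` is zero.
#' @examples
#' percent_change(70.7, 58.5)  # -17.3
#' @export
percent_change <- function(mean_A, mean_B) {
  if (any(mean_A == 0, na.rm = TRUE)) {
    warning("percent change undefined for zero reference mean")
    return(ifelse(mean_A == 0, NA_real_,
                  round((mean_B - mean_A) / mean_A * 100, 1)))
  }
  round((mean_B - mean_A) / mean_A * 100, 1)
}

#' Significance tiers
#'
#' @param p Numeric vector of p-values.
#' @return Factor with levels `ns`, `*`, `**`, `***` at thresholds
#'   p <= 0.05, 0.01, 0.001.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"))
}

#' Compare two groups of section profiles species by species
#'
#' Multiple unpaired two-sample t-tests on section-level percentages
#' (pooled variance by default; Welch selectable). Raw p-values are
#' reported by default; Benjamini-Hochberg adjustment is available behind
#' `p_adjust`. When both groups are degenerate (zero variance) with equal
#' means the statistic is 0 and p = 1.
#'
#' @param profiles_A,profiles_B Lists of [class_percentages()] data.frames
#'   (one per section) for the reference and comparison group.
#' @param group_names Length-2 character vector of group labels.
#' @param var_equal Pooled-variance t-test when `TRUE` (default); Welch
#'   otherwise.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"none"`).
#' @return data.frame with per-species group means, SEMs, percent change,
#'   t statistic, p-value and significance stars.
#' @export
compare_groups <- function(profiles_A, profiles_B,
                           group_names = c("A", "B"),
                           var_equal = TRUE, p_adjust = "none") {
  agg_A <- aggregate_group(profiles_A)
  agg_B <- aggregate_group(profiles_B)
  pull <- function(profiles, cls, sp) {
    vapply(profiles, function(p) {
      v <- p$percent[p$lipid_class == cls & p$species == sp]
      if (length(v) == 1) v else NA_real_
    }, numeric(1))
  }
  shared <- merge(agg_A[, c("lipid_class", "species")],
                  agg_B[, c("lipid_class", "species")])
  out <- do.call(rbind, lapply(seq_len(nrow(shared)), function(i) {
    cls <- shared$lipid_class[i]; sp <- shared$species[i]
    xa <- pull(profiles_A, cls, sp); xa <- xa[!is.na(xa)]
    xb <- pull(profiles_B, cls, sp); xb <- xb[!is.na(xb)]
    if (length(xa) < 2 || length(xb) < 2) {
      stop("each group needs >= 2 sections per species (", sp, ")",
           call. = FALSE)
    }
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      tt <- list(statistic = c(t = if (mean(xa) == mean(xb)) 0 else Inf),
                 p.value = if (mean(xa) == mean(xb)) 1 else 0)
    } else {
      tt <- stats::t.test(xb, xa, var.equal = var_equal)
    }
    data.frame(
      lipid_class = cls, species = sp,
      mean_A = mean(xa), sem_A = stats::sd(xa) / sqrt(length(xa)),
      mean_B = mean(xb), sem_B = stats::sd(xb) / sqrt(length(xb)),
      percent_change = percent_change(mean(xa), mean(xb)),
      t_statistic = unname(tt$statistic),
      p_value = tt$p.value,
      stringsAsFactors = FALSE
    )
  }))
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$stars <- as.character(significance_stars(out$p_value))
  names(out)[names(out) == "mean_A"] <- paste0("mean_", group_names[1])
  names(out)[names(out) == "sem_A"] <- paste0("sem_", group_names[1])
  names(out)[names(out) == "mean_B"] <- paste0("mean_", group_names[2])
  names(out)[names(out) == "sem_B"] <- paste0("sem_", group_names[2])
  attr(out, "group_names") <- group_names
  rownames(out) <- NULL
  out
}

#' Per-tissue class percentages for one section, end to end
#'
#' Preprocesses a cube, segments it, matches segments against the phantom
#' mask, merges segments by their tissue assignment, and returns one
#' class-percentage profile per tissue type.
#'
#' @param cube An [msi_datacube()].
#' @param phantom The section's [make_phantom()] phantom (or label matrix).
#' @param k Number of segments (default 3).
#' @param panel Annotation panel.
#' @param tolerance_ppm,threshold_fraction,max_ppm Pipeline parameters.
#' @param min_segment_size Passed to [hdrca_segment()].
#' @return Named list of [class_percentages()] data.frames keyed by tissue
#'   type; attribute `"match"` carries the segment-mask agreement report.
#' @export
tissue_profiles <- function(cube, phantom, k = 3, panel = default_panel(),
                            tolerance_ppm = 5, threshold_fraction = 0.005,
                            max_ppm = 9, min_segment_size = 10) {
  fm <- preprocess_cube(cube, tolerance_ppm = tolerance_ppm,
                        threshold_fraction = threshold_fraction)
  seg <- hdrca_segment(fm, k = k, min_segment_size = min_segment_size)
  match <- match_segments_to_mask(seg, phantom)
  ann <- annotate_features(fm, panel = panel, max_ppm = max_ppm)
  tissues <- unique(match$tissue_of_pixel)
  out <- lapply(tissues, function(ts) {
    class_percentages(fm, ann, pixels = which(match$tissue_of_pixel == ts))
  })
  names(out) <- tissues
  attr(out, "match") <- match
  out
}

#' Export profiles or comparisons as tidy TSV
#'
#' @param x data.frame (profile, aggregate or comparison table).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tidy_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
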
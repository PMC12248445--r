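#' @title Synthetic bronchial-biopsy datacube simulator
#' @description Ground-truthed MSI datacubes emulating bronchoscopic biopsy
#'   sections: tissue phantoms (epithelium, cellular stroma, fibrous
#'   stroma), region-specific lipid-class percentage profiles seeded from
#'   published group means, per-pixel total-ion-current variation, ppm-scale
#'   m/z jitter and random noise peaks.
#' @name synthetic_data
NULL

.TISSUE_LABELS <- c(background = 0L, epithelium = 1L,
                    cellular_stroma = 2L, fibrous_stroma = 3L)

#' Tissue label codes
#' @return Named integer vector mapping tissue names to mask labels.
#' @export
tissue_labels <- function() .TISSUE_LABELS

#' Acquisition / noise parameters for the simulator
#'
#' @param mz_range Acquisition window in Da (default the 550--1000 Da
#'   scanning range).
#' @param ppm_jitter_sd Gaussian m/z jitter, ppm (default 2; must stay
#'   below the 9 ppm annotation bound).
#' @param tic_lognormal_sd Log-normal sd of the per-pixel total-ion-current
#'   factor (default 0.3).
#' @param pixel_dirichlet_concentration Dirichlet concentration controlling
#'   between-pixel compositional variation (default 200; `Inf` = no
#'   variation).
#' @param noise_peak_rate Poisson mean of random noise peaks per spectrum
#'   (default 10).
#' @param noise_intensity_fraction Mean noise-peak intensity as a fraction
#'   of the median true-peak intensity (default 0.02).
#' @return Object of class `acquisition_params`.
#' @export
acquisition_params <- function(mz_range = c(550, 1000),
                               ppm_jitter_sd = 2,
                               tic_lognormal_sd = 0.3,
                               pixel_dirichlet_concentration = 200,
                               noise_peak_rate = 10,
                               noise_intensity_fraction = 0.02) {
  if (ppm_jitter_sd >= 9) stop("ppm_jitter_sd must be < 9", call. = FALSE)
  if (mz_range[1] < 550 || mz_range[2] > 1000 || mz_range[1] >= mz_range[2]) {
    stop("mz_range must lie within [550, 1000]", call. = FALSE)
  }
  structure(list(mz_range = as.numeric(mz_range),
                 ppm_jitter_sd = ppm_jitter_sd,
                 tic_lognormal_sd = tic_lognormal_sd,
                 pixel_dirichlet_concentration = pixel_dirichlet_concentration,
                 noise_peak_rate = noise_peak_rate,
                 noise_intensity_fraction = noise_intensity_fraction),
            class = "acquisition_params")
}

#' Noise-free acquisition parameters
#'
#' Degenerate settings (no jitter, no TIC variation, infinite Dirichlet
#' concentration, no noise peaks) under which the downstream pipeline must
#' recover the generator's profiles exactly.
#' @return An [acquisition_params()] object.
#' @export
noise_free_params <- function() {
  acquisition_params(ppm_jitter_sd = 0, tic_lognormal_sd = 0,
                     pixel_dirichlet_concentration = Inf,
                     noise_peak_rate = 0, noise_intensity_fraction = 0)
}

#' Build a tissue phantom
#'
#' Deterministic label grids emulating a biopsy section. The `banded`
#' layout places an epithelial band over cellular stroma over fibrous
#' stroma inside a rounded (superelliptical) tissue outline; `nested`
#' places epithelium as the outer shell around cellular then fibrous
#' stroma; `from_mask` adopts a supplied label grid unchanged.
#'
#' @param rows,cols Grid dimensions (each >= 16).
#' @param layout One of `"banded"`, `"nested"`, `"from_mask"`.
#' @param mask Integer label matrix, required for `layout = "from_mask"`.
#' @param pixel_size Raster size in micrometres (default 25).
#' @return Object of class `tissue_phantom` with elements `label_grid` and
#'   `pixel_size`.
#' @export
make_phantom <- function(rows, cols, layout = c("banded", "nested", "from_mask"),
                         mask = NULL, pixel_size = 25) {
  layout <- match.arg(layout)
  if (layout == "from_mask") {
    if (is.null(mask)) stop("from_mask layout needs a mask", call. = FALSE)
    grid <- matrix(as.integer(mask), nrow(mask), ncol(mask))
    if (!all(grid %in% .TISSUE_LABELS)) {
      stop("mask contains labels outside 0-3", call. = FALSE)
    }
    return(structure(list(label_grid = grid, pixel_size = pixel_size),
                     class = "tissue_phantom"))
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 16 || cols < 16) stop("phantom must be at least 16x16",
                                   call. = FALSE)
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  a <- rows / 2 - 1; b <- cols / 2 - 1
  rr <- matrix(seq_len(rows), rows, cols)
  cm <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  # superellipse (exponent 4) gives the rounded-slab outline of a biopsy
  u <- (abs(rr - cr) / a)^4 + (abs(cm - cc) / b)^4
  tissue <- u <= 1
  grid <- matrix(.TISSUE_LABELS[["background"]], rows, cols)
  if (layout == "banded") {
    tissue_rows <- range(which(rowSums(tissue) > 0))
    span <- tissue_rows[2] - tissue_rows[1] + 1
    e_max <- tissue_rows[1] + ceiling(0.28 * span) - 1
    cs_max <- tissue_rows[1] + ceiling(0.63 * span) - 1
    grid[tissue & rr <= e_max] <- .TISSUE_LABELS[["epithelium"]]
    grid[tissue & rr > e_max & rr <= cs_max] <-
      .TISSUE_LABELS[["cellular_stroma"]]
    grid[tissue & rr > cs_max] <- .TISSUE_LABELS[["fibrous_stroma"]]
  } else {
    grid[tissue & u > 0.45] <- .TISSUE_LABELS[["epithelium"]]
    grid[tissue & u <= 0.45 & u > 0.12] <- .TISSUE_LABELS[["cellular_stroma"]]
    grid[tissue & u <= 0.12] <- .TISSUE_LABELS[["fibrous_stroma"]]
  }
  structure(list(label_grid = grid, pixel_size = pixel_size),
            class = "tissue_phantom")
}

#' Construct a region lipid profile
#'
#' @param classes Named list: lipid class -> named numeric vector of
#'   species percentages (percent of the class total; each class must sum
#'   to 100 within 1e-6).
#' @param class_weights Named numeric vector of relative total-intensity
#'   shares per class (normalized to sum 1).
#' @param assumed Character vector of species labels whose values are
#'   assumed (not printed in the source group tables).
#' @return Object of class `region_profile`.
#' @export
region_profile <- function(classes, class_weights, assumed = character()) {
  for (cls in names(classes)) {
    p <- classes[[cls]]
    if (any(p < 0)) stop("negative percentage in class ", cls, call. = FALSE)
    if (abs(sum(p) - 100) > 1e-6) {
      stop("class ", cls, " percentages sum to ", sum(p), ", not 100",
           call. = FALSE)
    }
  }
  class_weights <- class_weights / sum(class_weights)
  structure(list(classes = classes, class_weights = class_weights,
                 assumed = assumed),
            class = "region_profile")
}

# DHA (22:6)-carrying species depleted in stroma relative to epithelium
.DHA_SPECIES <- c("PE 38:6", "PE 40:6", "PE P 38:6", "PE P 40:6", "PS 40:6")

# epithelial -> stromal profile: arachidonic-acid carriers (PI 38:4,
# PE 38:4) multiplied by `aa_fold` (capped so the class can still close to
# 100), DHA carriers retained at `dha_retain`, every other species scaled
# proportionally to fill the class to 100
.derive_stroma <- function(epi, aa_fold, dha_retain, class_weights) {
  classes <- lapply(names(epi$classes), function(cls) {
    p <- epi$classes[[cls]]
    fixed <- numeric(0)
    aa <- paste(gsub("_", " ", cls), "38:4")
    if (cls %in% c("PI", "PE") && aa %in% names(p)) {
      fixed[aa] <- min(aa_fold * p[[aa]], 80)
    }
    dha <- intersect(.DHA_SPECIES, names(p))
    for (s in dha) fixed[s] <- dha_retain * p[[s]]
    others <- setdiff(names(p), names(fixed))
    rest <- 100 - sum(fixed)
    if (rest < 0) stop("stromal profile cannot close class ", cls,
                       call. = FALSE)
    out <- p
    out[names(fixed)] <- fixed
    out[others] <- p[others] * rest / sum(p[others])
    out
  })
  names(classes) <- names(epi$classes)
  region_profile(classes, class_weights,
                 assumed = unique(c(epi$assumed, "stromal profile derived")))
}

# epithelial group tables; values printed in the source study's group
# comparisons are used verbatim, the remaining species carry assumed
# percentages filling each class to 100 (flagged in `assumed`)
.EPITHELIUM_TABLES <- list(
  non_tumor = list(
    PI = c("PI 38:4" = 41.5, "PI 36:2" = 12.5, "PI 34:2" = 5.9,
           "PI 34:1" = 13.7, "PI 32:0" = 1.8, "PI 36:4" = 8.2,
           "PI 38:3" = 8.2, "PI 36:1" = 8.2),
    PE = c("PE 38:4" = 14.5, "PE 36:4" = 1.3, "PE 36:1" = 31.0,
           "PE 36:2" = 18.8, "PE 38:2" = 12.0, "PE 38:6" = 11.2,
           "PE 40:6" = 11.2),
    PE_P = c("PE P 36:1" = 25.0, "PE P 38:4" = 20.0, "PE P 38:6" = 30.0,
             "PE P 40:6" = 25.0),
    PS = c("PS 36:1" = 25.0, "PS 38:4" = 30.0, "PS 40:6" = 45.0),
    SM = c("SM d34:1" = 70.7, "SM d36:1" = 12.0, "SM d42:1" = 7.3,
           "SM d42:2" = 10.0)
  ),
  tumor = list(
    PI = c("PI 38:4" = 67.3, "PI 36:2" = 5.3, "PI 34:2" = 1.8,
           "PI 34:1" = 3.8, "PI 32:0" = 0.3, "PI 36:4" = 7.2,
           "PI 38:3" = 7.2, "PI 36:1" = 7.1),
    PE = c("PE 38:4" = 27.7, "PE 36:4" = 2.2, "PE 36:1" = 25.9,
           "PE 36:2" = 16.1, "PE 38:2" = 12.0, "PE 38:6" = 8.1,
           "PE 40:6" = 8.0),
    PE_P = c("PE P 36:1" = 12.6, "PE P 38:4" = 23.6, "PE P 38:6" = 33.8,
             "PE P 40:6" = 30.0),
    PS = c("PS 36:1" = 33.2, "PS 38:4" = 44.7, "PS 40:6" = 22.1),
    SM = c("SM d34:1" = 58.5, "SM d36:1" = 17.0, "SM d42:1" = 10.5,
           "SM d42:2" = 14.0)
  ),
  control = list(
    PI = c("PI 38:4" = 30.0, "PI 36:2" = 14.0, "PI 34:2" = 8.0,
           "PI 34:1" = 9.0, "PI 32:0" = 2.0, "PI 36:4" = 12.0,
           "PI 38:3" = 12.0, "PI 36:1" = 13.0),
    PE = c("PE 38:4" = 12.0, "PE 36:4" = 1.5, "PE 36:1" = 30.0,
           "PE 36:2" = 20.0, "PE 38:2" = 13.0, "PE 38:6" = 12.0,
           "PE 40:6" = 11.5),
    PE_P = c("PE P 36:1" = 26.0, "PE P 38:4" = 18.0, "PE P 38:6" = 30.0,
             "PE P 40:6" = 26.0),
    PS = c("PS 36:1" = 26.0, "PS 38:4" = 29.0, "PS 40:6" = 45.0),
    SM = c("SM d34:1" = 68.0, "SM d36:1" = 13.0, "SM d42:1" = 8.5,
           "SM d42:2" = 10.5)
  ),
  smoker = list(
    PI = c("PI 38:4" = 31.0, "PI 36:2" = 14.0, "PI 34:2" = 8.0,
           "PI 34:1" = 7.2, "PI 32:0" = 2.0, "PI 36:4" = 12.0,
           "PI 38:3" = 12.3, "PI 36:1" = 13.5),
    PE = c("PE 38:4" = 13.5, "PE 36:4" = 1.5, "PE 36:1" = 29.5,
           "PE 36:2" = 19.0, "PE 38:2" = 13.0, "PE 38:6" = 12.0,
           "PE 40:6" = 11.5),
    PE_P = c("PE P 36:1" = 26.0, "PE P 38:4" = 18.0, "PE P 38:6" = 30.0,
             "PE P 40:6" = 26.0),
    PS = c("PS 36:1" = 26.0, "PS 38:4" = 29.0, "PS 40:6" = 45.0),
    SM = c("SM d34:1" = 68.0, "SM d36:1" = 13.0, "SM d42:1" = 8.5,
           "SM d42:2" = 10.5)
  ),
  copd = list(
    PI = c("PI 38:4" = 30.0, "PI 36:2" = 9.5, "PI 34:2" = 8.0,
           "PI 34:1" = 9.0, "PI 32:0" = 2.0, "PI 36:4" = 9.0,
           "PI 38:3" = 23.9, "PI 36:1" = 8.6),
    PE = c("PE 38:4" = 16.8, "PE 36:4" = 1.5, "PE 36:1" = 31.9,
           "PE 36:2" = 15.3, "PE 38:2" = 9.6, "PE 38:6" = 12.7,
           "PE 40:6" = 12.2),
    PE_P = c("PE P 36:1" = 26.0, "PE P 38:4" = 18.0, "PE P 38:6" = 30.0,
             "PE P 40:6" = 26.0),
    PS = c("PS 36:1" = 30.8, "PS 38:4" = 16.0, "PS 40:6" = 53.2),
    SM = c("SM d34:1" = 68.0, "SM d36:1" = 13.0, "SM d42:1" = 8.5,
           "SM d42:2" = 10.5)
  )
)

.ASSUMED_SPECIES <- c(
  "PI 36:4", "PI 38:3", "PI 36:1", "PE 38:2", "PE 38:6", "PE 40:6",
  "PE P 36:1", "PE P 38:4", "PE P 38:6", "PE P 40:6",
  "PS 36:1", "SM d36:1", "SM d42:1", "SM d42:2"
)

# class-level shares of total ion current per tissue type (assumed; the
# differences between regions feed the segmentation contrast)
.CLASS_WEIGHTS <- list(
  epithelium      = c(PE = 0.30, PI = 0.20, PE_P = 0.15, PS = 0.12, SM = 0.23),
  cellular_stroma = c(PE = 0.32, PI = 0.24, PE_P = 0.14, PS = 0.12, SM = 0.18),
  fibrous_stroma  = c(PE = 0.25, PI = 0.20, PE_P = 0.12, PS = 0.15, SM = 0.28)
)

#' Study groups
#' @return Character vector of the five study group names.
#' @export
study_groups <- function() names(.EPITHELIUM_TABLES)

#' Ground-truth lipid profiles per tissue region for a study group
#'
#' Epithelial per-class species percentages use the published group values
#' where printed (e.g. tumor epithelium PI 38:4 = 67.3 %, non-tumor
#' SM d34:1 = 70.7 %); species the source tables do not print carry
#' assumed values filling each class to 100 and are flagged in the
#' profile's `assumed` field. Stromal profiles are derived from the
#' epithelial ones: arachidonic-acid carriers PI 38:4 and PE 38:4 at
#' 2.2-fold (cellular stroma) / 2.05-fold (fibrous stroma) the epithelial
#' percentage, DHA carriers retained at 45 % / 20 %, everything else
#' rescaled so each class sums to 100.
#'
#' @param group One of [study_groups()].
#' @return Named list with `region_profile` entries `epithelium`,
#'   `cellular_stroma` and `fibrous_stroma`.
#' @examples
#' default_group_profiles("tumor")$epithelium$classes$PI[["PI 38:4"]]  # 67.3
#' @export
default_group_profiles <- function(group) {
  group <- as.character(group)
  if (!group %in% names(.EPITHELIUM_TABLES)) {
    stop("unknown group: ", group, call. = FALSE)
  }
  epi <- region_profile(.EPITHELIUM_TABLES[[group]],
                        .CLASS_WEIGHTS$epithelium,
                        assumed = .ASSUMED_SPECIES)
  list(
    epithelium = epi,
    cellular_stroma = .derive_stroma(epi, aa_fold = 2.2, dha_retain = 0.45,
                                     .CLASS_WEIGHTS$cellular_stroma),
    fibrous_stroma = .derive_stroma(epi, aa_fold = 2.05, dha_retain = 0.20,
                                    .CLASS_WEIGHTS$fibrous_stroma)
  )
}

# Dirichlet draw via independent gammas; infinite concentration collapses
# to the mean (noise-free limit)
.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g[alpha == 0] <- 0
  s <- sum(g)
  if (s == 0) return(alpha / sum(alpha))
  g / s
}

#' Sample one pixel spectrum from a region profile
#'
#' Species fractions within each lipid class are drawn from a Dirichlet
#' centred on the region profile, scaled by the class TIC share and a
#' log-normal per-pixel TIC factor, emitted at the species' theoretical
#' adduct m/z perturbed by Gaussian ppm jitter, and topped up with
#' Poisson-count noise peaks at uniform random m/z. Draws consume the
#' current R random number stream.
#'
#' @param profile A [region_profile()].
#' @param coord 0-based `(row, col)` of the pixel.
#' @param params An [acquisition_params()].
#' @param panel Annotation panel supplying theoretical m/z per species
#'   (default [default_panel()]).
#' @return A [pixel_spectrum()].
#' @export
sample_pixel_spectrum <- function(profile, coord,
                                  params = acquisition_params(),
                                  panel = default_panel()) {
  theo <- stats::setNames(panel$mz_theoretical, panel$species)
  conc <- params$pixel_dirichlet_concentration
  mz <- numeric(0); inten <- numeric(0)
  for (cls in names(profile$classes)) {
    p <- profile$classes[[cls]]
    missing <- setdiff(names(p), names(theo))
    if (length(missing) > 0) {
      stop("species absent from panel: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    frac <- if (is.infinite(conc)) p / 100 else .rdirichlet1(conc * p / 100)
    w <- profile$class_weights[[cls]]
    mz <- c(mz, theo[names(p)])
    inten <- c(inten, w * frac)
  }
  tic_factor <- if (params$tic_lognormal_sd > 0) {
    stats::rlnorm(1, 0, params$tic_lognormal_sd)
  } else 1
  inten <- inten * tic_factor
  if (params$ppm_jitter_sd > 0) {
    mz <- mz * (1 + stats::rnorm(length(mz), 0, params$ppm_jitter_sd) / 1e6)
  }
  keep <- inten > 0
  mz <- mz[keep]; inten <- inten[keep]
  if (params$noise_peak_rate > 0) {
    k <- stats::rpois(1, params$noise_peak_rate)
    if (k > 0) {
      nmz <- stats::runif(k, params$mz_range[1], params$mz_range[2])
      nint <- stats::rexp(k) * params$noise_intensity_fraction *
        stats::median(inten)
      mz <- c(mz, nmz); inten <- c(inten, nint)
    }
  }
  o <- order(mz)
  mz <- mz[o]; inten <- inten[o]
  # collapse pathological exact ties so the mz axis stays strictly ascending
  if (anyDuplicated(mz)) {
    inten <- as.numeric(tapply(inten, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  pixel_spectrum(mz, inten, coord)
}

#' Simulate one tissue section
#'
#' Emits one spectrum per non-background phantom pixel (row-major order)
#' and returns the datacube together with a ground-truth bundle (phantom,
#' per-region profiles, species m/z table).
#'
#' @param phantom A [make_phantom()] phantom.
#' @param group_profiles Named list of [region_profile()]s covering every
#'   non-background label present (as from [default_group_profiles()]).
#' @param params An [acquisition_params()].
#' @param panel Annotation panel (default [default_panel()]).
#' @param seed Optional integer; when given, seeds the RNG so the section
#'   is reproducible.
#' @return List with elements `cube` ([msi_datacube()]) and `truth`
#'   (phantom, profiles, species table, seed).
#' @export
simulate_section <- function(phantom, group_profiles,
                             params = acquisition_params(),
                             panel = default_panel(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- phantom$label_grid
  present <- setdiff(sort(unique(as.integer(grid))), 0L)
  lab_names <- names(.TISSUE_LABELS)[match(present, .TISSUE_LABELS)]
  missing <- setdiff(lab_names, names(group_profiles))
  if (length(missing) > 0) {
    stop("no profile for region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  spectra <- list()
  idx <- 1L
  for (r in seq_len(nrow(grid))) {
    for (cl in seq_len(ncol(grid))) {
      lab <- grid[r, cl]
      if (lab == 0L) next
      region <- names(.TISSUE_LABELS)[match(lab, .TISSUE_LABELS)]
      spectra[[idx]] <- sample_pixel_spectrum(
        group_profiles[[region]], coord = c(r - 1L, cl - 1L),
        params = params, panel = panel)
      idx <- idx + 1L
    }
  }
  cube <- msi_datacube(spectra, dim(grid), pixel_size = phantom$pixel_size)
  truth <- list(phantom = phantom, profiles = group_profiles,
                species_table = panel[, c("species", "lipid_class",
                                          "mz_theoretical")],
                seed = seed)
  list(cube = cube, truth = truth)
}

# between-subject jitter: Gaussian on logit fractions, renormalized so each
# class still sums to 100; sd = 0 reproduces the group profile exactly
.jitter_profile <- function(profile, sd) {
  if (sd <= 0) return(profile)
  classes <- lapply(profile$classes, function(p) {
    q <- p / 100
    pos <- q > 0 & q < 1
    z <- log(q[pos] / (1 - q[pos])) + stats::rnorm(sum(pos), 0, sd)
    q[pos] <- 1 / (1 + exp(-z))
    100 * q / sum(q)
  })
  region_profile(classes, profile$class_weights, profile$assumed)
}

#' Simulate a cohort of sections across study groups
#'
#' Section seeds are derived deterministically from the master seed;
#' per-section profiles are jittered around the group defaults by a
#' Gaussian on logit species fractions (between-subject variation).
#'
#' @param groups Named integer vector of sections per group; default the
#'   published cohort (tumor 5, non-tumor 5, COPD 4, smoker 5, control 4).
#' @param rows,cols Phantom dimensions per section (default 64).
#' @param layout Phantom layout (default `"banded"`).
#' @param params An [acquisition_params()].
#' @param panel Annotation panel.
#' @param subject_sd Between-subject logit-scale sd (default 0.08, chosen
#'   to yield group SEMs of order 0.5--1.5 percentage points at n = 4-5).
#' @param seed Master seed (integer).
#' @return List of sections; each element carries `group`, `section_seed`,
#'   `cube` and `truth`.
#' @export
simulate_cohort <- function(groups = c(tumor = 5, non_tumor = 5, copd = 4,
                                       smoker = 5, control = 4),
                            rows = 64, cols = 64, layout = "banded",
                            params = acquisition_params(),
                            panel = default_panel(),
                            subject_sd = 0.08, seed = 1) {
  if (any(groups <= 0)) stop("group sizes must be positive", call. = FALSE)
  phantom <- make_phantom(rows, cols, layout)
  sections <- list()
  idx <- 0L
  for (g in names(groups)) {
    base <- default_group_profiles(g)
    for (i in seq_len(groups[[g]])) {
      idx <- idx + 1L
      section_seed <- (as.integer(seed) + idx * 9973L) %% 2147483647L
      set.seed(section_seed)
      profs <- lapply(base, .jitter_profile, sd = subject_sd)
      sec <- simulate_section(phantom, profs, params = params, panel = panel)
      sections[[idx]] <- list(group = g, section_seed = section_seed,
                              cube = sec$cube, truth = sec$truth)
    }
  }
  sections
}

#' Serialize a ground-truth bundle
#'
#' Writes the phantom label grid as TSV and the profiles plus species
#' table as JSON next to it.
#'
#' @param truth Ground-truth bundle from [simulate_section()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_mask(truth$phantom$label_grid,
                   file.path(dir, "label_grid.tsv"))
  payload <- list(
    pixel_size = truth$phantom$pixel_size,
    seed = truth$seed,
    species_table = truth$species_table,
    profiles = lapply(truth$profiles, function(p) {
      list(classes = lapply(p$classes, as.list),
           class_weights = as.list(p$class_weights),
           assumed = p$assumed)
    })
  )
  jsonlite::write_json(payload, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
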
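---
title: "Methods: spatial lipidomics of bronchial biopsies with lungmsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial lipidomics of bronchial biopsies with lungmsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungmsi)
```

## The problem

MALDI mass spectrometry imaging (MSI) records one centroided mass spectrum
per raster position on a tissue section. In negative-ion mode with a DAN
matrix, the 550–1000 Da window captures the glycerophospholipid and
sphingomyelin repertoire of bronchial biopsies — PE, ether PE (alkyl PE O
and plasmalogen PE P), PI, PS and SM. Because lipid composition is tightly
cell-type specific, clustering the pixel spectra recovers the histological
architecture of the biopsy (epithelium, cellular stroma, fibrous stroma),
and within-class percentage profiles of each tissue segment can then be
compared between study groups (control, smoker, COPD, lung-cancer tumor and
its paired non-tumor mucosa).

`lungmsi` implements that pipeline end to end and, because no public MSI
dataset of this design exists, ships a ground-truthed simulator so every
stage is testable.

## The mass panel

Species are named at the shorthand level, `class C:D` (total chain carbons
and double bonds, head group excluded; SM uses the `d` backbone
convention). Elemental compositions follow per-class backbone rules — for
example diacyl PE `C:D` is C(C+5) H(2C+10−2D) N O8 P — and monoisotopic
masses are summed from IUPAC atomic constants. Negative-mode detection uses
the deprotonated ion for the acidic glycerophospholipids. Sphingomyelin is
zwitterionic with a quaternary amine and no acidic proton, so its default
adduct is acetate, with chloride and demethylated forms selectable; the
acetate salt is the conventional choice where an ammonium acetate buffer is
part of the protocol.

A plasmalogen PE P `c:d` is exactly isobaric with the alkyl-ether PE O
`c:(d+1)` (the vinyl-ether double bond is not counted in the shorthand).
The panel assigns these peaks to PE P — in most tissues alkenyl-PE
dominates alkyl-PE — and records the suppressed alternative in an isobar
column so the convention stays auditable:

```{r}
panel <- default_panel()
panel[panel$lipid_class == "PE_P", c("species", "mz_theoretical",
                                     "isobar_alternative")]
```

## What the simulator emulates — and what it does not

`make_phantom()` draws a deterministic rounded-slab biopsy outline with an
epithelial band over cellular then fibrous stroma (or nested shells).
`default_group_profiles()` provides, per group and tissue type, within-class
species percentages. Where the published group comparisons print a value
(tumor epithelium PI 38:4 = 67.3 %, non-tumor 41.5 %; PE 38:4 = 27.7 vs
14.5 %; SM d34:1 = 58.5 vs 70.7 %, and the §3-style COPD shifts), those
values are used verbatim. Species the tables do not print receive assumed
percentages inside the stated qualitative ranges (e.g. PE 38:2 within
10–20 % of PE, minor PI species at 5–10 %) and are flagged `assumed` in the
profile metadata.

Stromal profiles are derived from the epithelial ones: the
arachidonic-acid carriers PI 38:4 and PE 38:4 at 2.2-fold (cellular) and
2.05-fold (fibrous) their epithelial percentage, DHA carriers (PE 38:6/40:6,
PE P 38:6/40:6, PS 40:6) retained at 45 % and 20 %, everything else
rescaled so each class closes to 100. One caveat decided at design time:
the published 2-fold stromal enrichment is expressed against total membrane
lipids, while this package encodes it on within-class percentages (the
quantity the rest of the pipeline works in). A control epithelial PI 38:4
above ~45 % would make a 2-fold within-class stroma impossible, so the
control epithelium uses an assumed 30 % rather than chaining the printed
inter-group percent changes, which were measured on a different scale.

The noise model has four independent knobs (`acquisition_params()`):

| parameter | default | meaning |
|---|---|---|
| `pixel_dirichlet_concentration` | 200 | between-pixel Dirichlet on species fractions (kept compositional; `Inf` = none) |
| `tic_lognormal_sd` | 0.3 | per-pixel total-ion-current factor |
| `ppm_jitter_sd` | 2 ppm | Gaussian m/z error, matching "typically < 3 ppm" accuracy |
| `noise_peak_rate` / `noise_intensity_fraction` | 10 / 0.02 | Poisson count of uniform noise peaks at ~2 % of the median true peak |

Between-subject variation in `simulate_cohort()` is Gaussian on logit
species fractions (sd 0.08), renormalized per class. That default was
chosen once, a priori, to give group SEMs of order 0.5–1.5 percentage
points at n = 4–5 sections — the order of the published error bars, which
are readable only from figures. The default cohort is the published design:
tumor 5, non-tumor 5, COPD 4, smoker 5, control 4 sections.

The simulator does **not** model profile-mode peak shape, isotopologue
envelopes, matrix cluster ions, detector saturation, spatial mixing at
region boundaries, or histology-correlated texture within a region. Passing
recovery tests therefore demonstrates that the pipeline's arithmetic and
clustering are correct under compositional noise — not that it would be
robust to every artifact of real acquisitions.

## Preprocessing

The chain is normalize → align → filter, in that order.

* **TIC normalization** divides each spectrum by its summed intensity and
  rescales by the cohort-mean TIC, so per-pixel sums are equal while the
  global scale is preserved. Zero-TIC pixels are dropped with a counted
  warning.
* **Alignment** pools all peaks, sorts them, and scans upward, opening a
  new feature whenever the next peak is more than `tolerance_ppm` (default
  5 ppm — between the typical <3 ppm accuracy and the 9 ppm assignment
  bound) from the running intensity-weighted centroid. Each pixel
  contributes at most one peak per feature; the most intense wins and ties
  break toward lower m/z. The greedy window scheme is deterministic,
  permutation-invariant over pixels, and its feature count is
  non-increasing in the tolerance — all asserted in tests.
* **The 0.5 % filter** drops features whose *dataset mean spectrum*
  intensity falls below 0.5 % of the strongest mean feature. Filtering the
  aggregate spectrum, not each pixel, keeps genuine low-abundance species
  present in all pixels and keeps class percentages comparable. Note an
  intrinsic consequence: a species at 0.3 % of a class whose top species
  holds 67 % of it sits below 0.5 % of the strongest peak *by
  construction*, so tumor PI 32:0 is removed at the default threshold and
  the remaining PI percentages renormalize upward by ~0.2 points. The
  zero-noise exactness checks therefore run with `threshold_fraction = 0`
  (the identity), and the filter's behavior is tested separately.

## Segmentation

`hdrca_segment()` is a hierarchical divisive scheme on rank-transformed
spectra: each pixel's feature vector is replaced by its within-pixel ranks
(ties averaged), making the partition invariant to any positive rescaling
of intensities; heterogeneity is the sum of squared rank deviations from
the segment mean. Starting from one segment, the most heterogeneous
splittable segment is bisected by 2-means until `k` segments exist.

The bisection is initialized deterministically with centers one standard
deviation apart along the segment's first principal component. A
farthest-pair initialization was evaluated first and rejected: the two
mutually farthest pixels are near-certainly noise outliers of the same
tissue, and on default-noise tumor sections that start point failed to
separate epithelium from stroma (ARI ≈ 0 on some sections), whereas the
principal-component start recovers all three tissue types (ARI ≈ 0.95).
Splits that would produce a child below `min_segment_size` (default 10
pixels) are rejected; if no segment can be split, fewer than `k` segments
come back with a warning.

Because segment count is a mathematical choice, `k` may exceed the number
of tissue types (the published workflow inspects 5 and 10 segments but
ascribes biological meaning to 3). `match_segments_to_mask()` assigns each
segment its majority tissue type against a histology mask — the in-silico
stand-in for pathologist confirmation — reporting per-segment purity and
the adjusted Rand index; the pipeline then merges segments by tissue before
profiling.

## Profiles and statistics

Annotation matches each aligned feature to the panel entry minimizing
|ppm error| and accepts it below 9 ppm; unmatched features are flagged,
never silently dropped. Within each class, a species' percentage is its
summed intensity over the pixel subset divided by the class total, × 100
(intensity-weighted; at zero noise this equals the mean of per-pixel
percentages, asserted in tests). Sections — not pixels — are the unit of
replication: group means carry SEM = sd/√n over sections, and group
comparisons are per-species unpaired t-tests (pooled variance by default,
Welch selectable) with tiered stars at p ≤ 0.05/0.01/0.001. Raw p-values
are reported by default to mirror the published captions;
Benjamini–Hochberg is available behind `p_adjust = "BH"`. Percent changes
`(B − A)/A × 100` are rounded to one decimal, which reproduces the printed
worked examples, e.g. `percent_change(70.7, 58.5)` = −17.3.

## Numerical choices and degenerate inputs

* Atomic masses are compile-time constants; no element-table dependency.
* Exact m/z ties in a simulated spectrum are collapsed by summing so the
  m/z axis stays strictly ascending.
* A class whose total intensity is zero reports its species as missing
  (`NA`), never 0/0; an all-identical cube returns one segment with a
  warning; degenerate t-tests (zero variance in both groups, equal means)
  return t = 0, p = 1.
* imzML I/O writes processed (centroided) mode only: m/z as 64-bit floats,
  intensities as 32-bit floats, 0-based row/col in memory mapped to the
  format's 1-based x/y. The writer is validated against an independent
  Python imzML parser in the test suite.

## Problem sizes used in the tests

The packaged checks run on 64×64-pixel phantoms (≈3,600 tissue spectra per
section, matching a 1.6 mm biopsy at 25 μm raster) for the end-to-end
recovery criteria and 16–32-pixel grids for unit tests; cohort checks use
5 sections per group. These sizes were chosen so the full suite documents
the method at realistic biopsy scale while remaining quick to run.

## Known limitations

* The divisive rank-based segmentation is this package's interpretation of
  hierarchical divisive clustering with rank robustness; the original
  algorithm's exact objective is not published in a reproducible form, so
  only its qualitative behavior (tissue-type recovery) can be verified.
* Simulated regions are internally homogeneous; real epithelium is a
  pseudostratified mixture whose segments could subdivide further at higher
  lateral resolution.
* Species identity is m/z-level only: isobaric overlaps beyond the PE P /
  PE O pair (which is ledgered explicitly) are not modeled, and no
  MS/MS-level confirmation is represented.
* Positive-mode classes (PC above all) are out of scope, as are absolute
  quantification and sn-position resolution.
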
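# lungmsi

Spatial lipidomics of human lung tissue by negative-ion MALDI mass
spectrometry imaging (MSI), for researchers studying how bronchial tissue
types — epithelium, cellular stroma, fibrous stroma — differ in their
membrane lipid composition, and how lung cancer and COPD remodel it.

MSI records one centroided spectrum per 25 μm raster position. `lungmsi`
turns those per-pixel peak lists into biology in four steps:

1. **Preprocess** — total-ion-current (TIC) normalization, greedy
   ppm-window peak alignment into a pixels × features matrix, and removal
   of features below 0.5 % of the strongest mean-spectrum peak.
2. **Segment** — hierarchical divisive clustering of rank-transformed
   pixel spectra (bisecting 2-means on within-pixel ranks, most
   heterogeneous segment first), then majority matching of segments to a
   histology mask.
3. **Annotate & profile** — features matched to a computed panel of PE,
   PE O/PE P, PI, PS and SM species within 9 ppm, and each species
   expressed as a percentage of its lipid class:
   for species *i* of class X, `Xi% = I_Xi / ΣI_X · 100`.
4. **Compare** — section-level profiles aggregated to group mean ± SEM and
   tested species-by-species with multiple unpaired t-tests
   (`*`/`**`/`***` at p ≤ 0.05/0.01/0.001).

Because no public dataset of this design exists, the package includes a
ground-truthed simulator (`make_phantom()`, `default_group_profiles()`,
`simulate_section()`, `simulate_cohort()`) whose tissue profiles encode the
published group percentages (e.g. epithelial PI 38:4 at 67.3 % of PI in
tumor vs 41.5 % in non-tumor tissue; ≥2-fold stromal enrichment of
arachidonic-acid species), plus Dirichlet pixel noise, log-normal TIC
variation, 2 ppm mass jitter and random noise peaks. Datacubes read and
write processed-mode imzML.

## Worked example

Simulate one tumor biopsy section, run the full pipeline, and look at the
epithelial PI profile:

```r
library(lungmsi)

phantom <- make_phantom(64, 64, "banded")
section <- simulate_section(phantom, default_group_profiles("tumor"), seed = 42)
profs   <- tissue_profiles(section$cube, phantom, k = 3)

epi <- profs$epithelium
epi[epi$lipid_class == "PI", ]
#>    lipid_class species percent n_pixels
#> 12          PI PI 34:1    3.92      990
#> 13          PI PI 34:2    1.78      990
#> 14          PI PI 36:1    7.02      990
#> 15          PI PI 36:2    5.21      990
#> 16          PI PI 36:4    7.15      990
#> 17          PI PI 38:3    7.23      990
#> 18          PI PI 38:4   67.70      990

attr(profs, "match")$assignment
#>   segment          tissue size purity
#> 1       1      epithelium  990  0.985
#> 2       2  fibrous_stroma 1220  0.980
#> 3       3 cellular_stroma 1366  0.970
```

The three lipid segments recover the three tissue types (purity ≥ 0.97,
adjusted Rand index 0.93 against the ground-truth mask), and the epithelial
PI profile lands on the simulated tumor truth: PI 38:4 at 67.7 % of the
class versus the seeded 67.3 %, with the residual from noise peaks and the
0.5 % intensity filter. Group-level comparisons follow the same pattern:

```r
percent_change(70.7, 58.5)   # SM d34:1, non-tumor -> tumor
#> [1] -17.3
```

`run_pipeline(default_config(), seed = 1, out_dir = "out")` runs the whole
cohort design (tumor 5 / non-tumor 5 / COPD 4 / smoker 5 / control 4
sections) and writes tidy TSV profiles and comparison tables; a thin
command-line wrapper lives at `inst/cli/lungmsi-pipeline.R`.

## Layout

- `R/` — mass panel (`lipid_db`), simulator (`synthetic_data`), imzML and
  mask I/O (`msi_io`), preprocessing, segmentation, profiles and
  statistics, pipeline driver and ion-image rendering.
- `vignettes/lung-msi-lipidomics.Rmd` — the methods vignette: model,
  assumptions, parameter defaults and their rationale, limitations.
- `tests/testthat/` — unit, property and end-to-end recovery tests; all
  fixtures are generated in code.
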
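Package: lungmsi
Title: Spatial Lipidomics of Lung Tissue by MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for negative-ion-mode MALDI mass
    spectrometry imaging (MSI) lipidomics of bronchial biopsy sections:
    a computed glycerophospholipid and sphingomyelin mass panel, a
    ground-truthed synthetic datacube simulator emulating bronchoscopic
    biopsies (epithelium, cellular stroma, fibrous stroma), imzML and
    label-mask input/output, total-ion-current normalization, ppm-window
    peak alignment, low-intensity filtering, hierarchical divisive
    rank-based segmentation of pixel spectra, ppm mass annotation,
    per-segment lipid-class percentage profiles, and between-group
    differential comparisons with unpaired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    xml2,
    jsonlite,
    yaml,
    png,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
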
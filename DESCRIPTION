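Package: morphozone
Title: Mapping Zones of Cancer Nuclear Morphological Diversification in
    Tissue Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spatial analysis of single-cell maps derived from whole-slide
    histology images. Tumor sections are partitioned into zones by Voronoi
    tessellation seeded on randomly selected cancer cells; per-zone
    variability of the nuclear shape factor is tested for spatial
    autocorrelation with the local Moran's I statistic under queen
    contiguity, with analytic or Monte-Carlo (Hope) significance and false
    discovery rate control, yielding per-zone diversification calls and
    sample-level summaries. Includes zonal microenvironment statistics
    (composition, ordered trend testing of lymphocytic infiltration,
    tumor-content-filtered marker correlation), cohort-level association
    tests, and a synthetic slide generator with planted diversification
    zones for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deldir,
    withr
Config/testthat/edition: 3
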
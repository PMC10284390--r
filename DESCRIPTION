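Package: oomat
Title: Quantitative Image Analysis of Zebrafish Oocyte Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cytoplasmic reorganization in maturing
    zebrafish oocytes from multi-channel fluorescence time-lapse images:
    segmentation and tracking of yolk granules, cortical granules, K+
    vesicles and Rab11 puncta; radial phase-fraction and granule-density
    profiles over the normalized oocyte radius; kymograph construction and
    slope velocimetry for granule, aster and ooplasmic flows; microtubule
    aster detection and Voronoi contraction-domain analysis with xi1/xi2
    percolation classification; and event-level metrics (fusion histograms,
    mean granule area, cortical-granule depletion, chorion elevation).
    Includes a seeded synthetic time-lapse generator that emulates the
    imaged biology (granule fusion with volume conservation, centripetal
    yolk compaction, outward cortical-granule advection, an animal-to-
    vegetal aster-formation wave) together with ground-truth tables, so the
    whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    class,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
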
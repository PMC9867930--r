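Package: macdev
Title: Macular Deviation-Map Quantification for Early Glaucoma Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies macular ganglion cell layer (GCL) and combined
    ganglion cell/inner plexiform layer (GCIPL) damage from OCT deviation
    maps and compares their diagnostic performance for early glaucoma.
    Provides a per-pixel Gaussian normative model with five-category
    percentile classification (abnormal at the 1% and 5% cutoffs,
    supernormal at the 95% and 99% cutoffs), a synthetic-eye and cohort
    simulator with arcuate and hemifield defect fields, 8 x 8 posterior-pole
    superpixel grids aggregated into superior/inferior macular sectors,
    pixel-extent quantification of rendered color deviation maps within the
    entire scan or a fitted perifoveal elliptical annulus (direct
    least-squares ellipse fitting, Hough-transform removal of sector overlay
    lines), and discrimination statistics: Mann-Whitney AUROC with DeLong
    variance, the DeLong paired ROC comparison, and Wilcoxon group tests,
    assembled into cohort summary tables and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
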
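Package: phenogrowth
Title: Machine-Vision Growth Analysis for Wheat Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based growth analysis for controlled-environment wheat
    phenotyping. Segments plant silhouettes from fluorescence-style grayscale
    images by Otsu thresholding and binary morphology, extracts side-projected
    area (SPA) and geometric traits calibrated to physical units, averages the
    12 rotational side views per plant, computes interval relative growth
    rates and compound-interest (exponential) growth fits, and validates SPA
    as a high-throughput surrogate for destructive traits via regression,
    correlation and balanced two-way ANOVA. Includes a synthetic-data
    generator for fluorescence-style plant images with ground-truth masks and
    for destructive growth-study trait tables, plus embedded reference tables
    from a two-genotype spring wheat growth study for end-to-end reproduction
    of the published growth statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
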
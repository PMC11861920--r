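Package: chromadens
Title: Densitometric Assessment of Sperm Chromatin Integrity in Stained
    Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis of sperm chromatin integrity from
    stained semen-smear micrographs. Segments sperm heads from brightfield
    images (toluidine blue or Feulgen stains), selects the lightest and most
    homogeneous heads as the per-sample staining reference, maps per-pixel
    intensity deficits against that reference, and classifies decompacted
    chromatin by its location within the head (base, basal half, central
    axis, base-apex, total, dispersed). Also provides rule-based grading of
    clear chromatin regions in transmission electron micrographs, red/green
    intensity calling for acridine-orange fluorescence images, a synthetic
    phantom generator with exact ground truth for validation, and the
    statistical layer used in bull fertility studies: in vitro embryo
    production (IVEP) rates with reference-bull normalization, Pearson
    correlation, Woolf odds ratios, pairwise proportion tests, and
    Scott-Knott clustering of treatment means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
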
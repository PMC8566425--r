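Package: mammilieu
Title: Quantification of Immune Cell Milieus in Multiplex IHC Breast Tissue
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for quantifying immune cell densities in
    brightfield multiplex immunohistochemistry (IHC) images of breast tissue.
    Provides a synthetic scene generator with ground truth, optical-density
    color deconvolution for chromogen separation, a two-stage encoder-decoder
    tissue segmenter (epithelium-enriched regions, then peri-epithelium versus
    intralobular stroma), blob-based cell detection with size and intensity
    filters, nucleus-associated macrophage classification, compartment-specific
    density estimation (cells per square millimeter), cohort-level statistics
    (age regressions, ANOVA with Tukey post-hoc tests, paired and unpaired
    comparisons), flow-cytometry gating of leukocyte subsets, and transcriptional
    immune-signature scoring with Holm-Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
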
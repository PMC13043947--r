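Package: stainbench
Title: Benchmarking Classical Stain Normalization for H&E Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing classical hematoxylin-and-eosin (H&E) stain
    normalization methods on multi-laboratory histology panels. Implements
    histogram matching, Reinhard colour transfer in the Ruderman l-alpha-beta
    space, Macenko singular-value stain estimation, and Vahadane sparse
    non-negative stain factorization, together with the red-to-blue ratio
    reference selection rule, histogram/PCA/k-means representative sample
    selection, a quantitative evaluation suite (histogram intersection,
    Pearson correlation, Euclidean distance, Jensen-Shannon divergence,
    SSIM, and a Frechet feature distance), and a seeded Beer-Lambert
    synthetic slide generator that emulates inter-laboratory staining
    variation with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
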
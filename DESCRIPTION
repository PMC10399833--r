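Package: facenorm
Title: Unsupervised Facial Anomaly Appraisal via Generative Face Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the severity of localized facial anomalies (such as cleft
    lip) without supervised training, by comparing a face photograph against a
    "normalized" counterpart synthesized from a generative face model.  The
    pipeline canonicalizes the input face (background adjustment, eye
    alignment, fixed inter-ocular scaling, square crop), projects it into a
    generator's latent space by perceptual-loss optimization with a
    noise-randomness regularizer, briefly fine-tunes the generator weights
    with the latent frozen to recover identity detail, and then derives
    pixelwise squared-error, SSIM or perceptual difference heatmaps (with
    optional YCbCr transformation and morphological erosion) whose masked
    energy yields an interpretable negative-log severity score.  Includes a
    CPU-scale differentiable toy generator, synthetic face/rating fixtures,
    and evaluation against human ratings via Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr
Config/testthat/edition: 3
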
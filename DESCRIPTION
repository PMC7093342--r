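Package: pleasurepairs
Title: Simulation and Model-Based Analysis of Pleasure Ratings for Image Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying whether observers can report the felt pleasure
    of one of two briefly glimpsed images, or their combined pleasure, without
    bias from the other image. Provides a deterministic generator for the
    counterbalanced two-image rating design (quintile-based stimulus selection,
    precued/postcued blocks, baseline block), synthetic observers with early
    (per-image) and late (response-stage) Gaussian noise under a weighted
    linear combination rule, exact constrained least-squares fitting of the
    model family (faithful, compulsory averaging, partial averaging,
    compressive, expansive) with leave-one-out cross-validation model
    comparison, error-based reliability statistics (Cronbach's alpha,
    absolute-agreement intraclass correlation, attenuation ceilings), and
    rating-variance analyses including the square-root-of-two averaging
    prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
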
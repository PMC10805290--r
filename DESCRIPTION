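Package: neurodim
Title: Latent Dimensionality and Encoding Performance of Representational Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric analysis of representational models of visual cortex:
    effective dimensionality (participation ratio) of activation eigenspectra,
    power-law spectrum fitting, a subspace-alignment simulation framework
    linking dimensionality and alignment pressure to cross-validated encoding
    performance, a neural encoding pipeline (PCA reduction, partial least
    squares or ordinary least squares regression, split-half noise ceilings,
    normalized encoding scores, representational similarity analysis),
    prototype-learning transfer to novel categories with mean reciprocal rank,
    and projection-distance concentration analysis. Includes seeded synthetic
    generators emulating the statistical structure of model activations and
    multi-trial neural recordings, so every analysis runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
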
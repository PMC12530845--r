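Package: luhq
Title: Land-Use Change Accounting, Habitat Quality and Scenario Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled land-use-change and habitat-quality analysis for categorical
    land-cover rasters: class-by-class transition matrices and change summaries,
    an InVEST-style habitat quality and degradation model with distance-decay
    threat kernels, Markov-chain land-demand projection with scenario-specific
    transition-probability adjustments, a simplified patch-generating cellular
    automata allocator honouring restricted-conversion (conservation redline)
    masks, and map-agreement validation metrics (overall accuracy, Cohen's kappa,
    figure of merit). Ships a seed-reproducible synthetic landscape generator so
    the full pipeline is testable without external data. Rasters are exchanged in
    the plain-text Esri ASCII grid format; tabular results are tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    ranger,
    EBImage,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
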
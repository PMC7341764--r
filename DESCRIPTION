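Package: snagmort
Title: Height-Structured Drought Mortality from Forest Inventories with Snag-Dated Death Years
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates 2014-2016 drought mortality by taxonomic group and tree
    height class from standing-tree inventories in which death years of snags
    are uncertain, and decomposes the height trend of pooled mortality into
    compositional and group-level components. Includes a synthetic forest
    inventory generator, species-specific allometric height-class assignment,
    gamma time-since-death models fitted to retention-class calibration data,
    a latent-indicator Metropolis-within-Gibbs sampler for per-cell mortality
    with death-date uncertainty propagated into credible intervals, and direct
    standardization counterfactuals that detect Simpson-type reversals between
    pooled and stratum-level mortality trends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
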
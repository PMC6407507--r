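Package: ipsexp
Title: Invasive Plant Expansion Potential in Ecoregions Under Climate Change
Version: 0.1.0
Authors@R:
    person("Maintainer", "ipsexp", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A presence-background species distribution modelling pipeline for
    assessing the potential of invasive plant species to expand into terrestrial
    and freshwater ecoregions under climate-change scenarios. Provides occurrence
    record quality control, collinearity screening of bioclimatic variable stacks,
    maximum-entropy (Gibbs density) suitability models with hinge features and L1
    regularisation, AUC and omission-rate model evaluation, multi-species
    suitability-change aggregation to ecoregions, jackknife variable importance,
    and per-biome regression summaries. Includes a synthetic-world generator
    (autocorrelated climate fields, tessellated ecoregions, Gaussian-niche
    species, contaminated occurrence sampling) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
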
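Package: rotimpact
Title: Multi-Function Sustainability Assessment of Diversified Crop Rotations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@rotimpact.org",
           role = c("aut", "cre"))
Description: Quantitative assessment of diversified crop rotation systems:
    wheat-equivalent yield, CPI-deflated economic benefit and protein yield;
    static-chamber N2O/CH4 flux calculation, trapezoidal integration and
    100-year global warming potential; life-cycle indirect emissions, soil
    organic carbon stocks by depth increment and the net greenhouse-gas
    budget; Cornell Soil Health Assessment scoring with PCA-derived
    indicator weights; OTU-table rarefaction and alpha-diversity indices;
    and an entropy-weighted TOPSIS comprehensive evaluation index. Includes
    a seeded synthetic experiment generator reproducing a randomized
    complete block rotation trial (six rotations, three replicates, six
    years) so the full pipeline can be exercised and validated without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
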
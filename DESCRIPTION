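Package: nutribal
Title: Compositional Nutrient Balance Diagnosis for Orchard Fertilization Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing plant nutrient status from tissue analyses
    treated as compositional data. Builds isometric log-ratio (ilr) balances
    from a sequential binary partition of nutrients and a filling value,
    classifies specimens into high- and low-yield classes with a weighted
    k-nearest-neighbour model tuned by cross-validation, partitions specimens
    into true/false negative/positive diagnostic groups, and back-transforms
    Monte-Carlo samples of balance confidence intervals into nutrient
    concentration ranges at high yield. Also compiles per-element fertilization
    budget sheets (inputs from organic amendments and mineral fertilizer,
    removals through harvested fruit) and provides a synthetic orchard data
    generator for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), class, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
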
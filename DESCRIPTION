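Package: tetragp
Title: Genomic Prediction and Inbreeding Analysis for Autotetraploid Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying inbreeding depression and genomic prediction in
    autotetraploid crops such as potato. Simulates tetrasomic inheritance with
    identity-by-descent tracking (including double reduction), generates
    augmented-design field trials with directional inbreeding depression,
    adjusts phenotypes with check-based block correction factors, builds
    dosage-based genomic relationship matrices for tetraploids, fits GBLUP by
    exact restricted maximum likelihood and by Gibbs sampling, and estimates
    genomic prediction accuracy under random and family-structured
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
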
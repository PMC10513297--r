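Package: ascpen
Title: Penetrance Estimation for Rare Variants under Family Ascertainment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates nuclear-family (sibship) data for a rare autosomal
    dominant variant under a generalized k-model of ascertainment, and
    quantifies the bias that ascertainment induces in penetrance estimates.
    Provides the naive carrier-counting estimator, the classical
    single-ascertainment ("drop one proband") correction, and a
    likelihood-based estimator obtained by maximizing the linkage-
    disequilibrium LOD score (the LD-MOD) over penetrances and Smith's
    admixture parameter. Also computes co-segregation evidence statistics
    for variant pathogenicity assessment: the linkage-equilibrium LOD
    evaluated at the MOD-maximizing model (LE-LOD(max)) and a
    proband-conditioned Bayes factor. Includes exact enumeration oracles
    for the counting estimators, a replicate-level experiment runner, and
    reader/writer support for LINKAGE pre-makeped pedigree files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
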
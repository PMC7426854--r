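Package: lethalrisk
Title: Genomic Prediction of Offspring Mortality Risk from Polygenic and
    Recessive Lethal Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the mortality risk of a breeding animal's
    future offspring by combining two genetic components that act on different
    scales: a polygenic liability, predicted by genomic BLUP under linear,
    probit or logit models and transformed into a risk probability, and
    recessive lethal alleles, whose transmitted risk follows from the sire's
    carrier status, the population allele frequency and the penetrance of each
    lethal locus. Includes a stochastic breeding-population simulator
    (overlapping generations, Haldane gene drop, liability-threshold
    phenotypes with per-locus lethal penetrance), VanRaden method-1 genomic
    relationship matrices, nine genomic mixed models, and a replicated
    validation workbench that measures risk-prediction accuracy and
    calibration against observed offspring mortality.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
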
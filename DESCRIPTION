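Package: diazoflux
Title: Marine Dinitrogen Fixation Rates and Diazotroph Community Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative workflow for pelagic nitrogen-fixation surveys that
    use the 15N2 bubble tracer method. Computes dissolved-N2 inventories and
    theoretical tracer enrichment with a dissolution correction, converts
    filter mass-spectrometry readouts to volumetric N2-fixation rates by
    isotope mass balance, and derives diazotroph nitrogen-release and
    Redfield carbon-support estimates. Companion community analytics cover
    nifH OTU-table filtering, rarefaction, Shannon diversity, relative
    abundance profiles and Bray-Curtis dissimilarity; distance-based linear
    modeling with permutation pseudo-F tests relates community structure to
    environmental predictors; and qPCR standard-curve fitting yields absolute
    gene-copy abundances. A forward simulator generates stations, communities,
    incubations and qPCR plates with known ground truth so the whole pipeline
    is testable end to end.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
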
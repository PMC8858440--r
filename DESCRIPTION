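Package: pathmeta
Title: Pathway-Centric Meta-Analysis of Untargeted Metabolomics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint, pathway-centric re-analysis of heterogeneous
    untargeted LC-MS metabolomics studies. Peak lists from different platforms
    are parsed into a uniform representation, features are putatively annotated
    by enumerating adduct forms and matching inferred neutral masses against a
    metabolic model within a ppm tolerance, and pathway activity is scored with
    an EASE-adjusted Fisher's exact test validated by permutation resampling.
    Compounds observed in several studies are merged with best p-value
    selection, shared dysregulated metabolites are reported per pathway, and
    user-supplied dysregulated gene and protein lists can be superimposed on
    the pathway results for systems-level interpretation. A deterministic
    synthetic-study generator with known spiked pathway enrichment supports
    power and calibration analysis without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
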
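Package: qmmfdr
Title: Entrapment-Query Mix-Max Estimation of False Discovery Rates for
    Peptide-Spectrum Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoy-free false discovery rate (FDR) estimation for shotgun
    proteomics search results. Implements the query mix-max (QMM) procedure,
    which deconvolves the observed sample score mixture into foreign-incorrect,
    native-incorrect and correct components using entrapment-query matches
    (spectra from a foreign organism searched against the sample database) as
    the null score sample, together with Storey pi0 estimation from
    entrapment-derived empirical p-values, the classical decoy-based mix-max
    and target-decoy competition baselines, and a simulation harness for
    verifying the calibration of FDR estimates against the known false
    discovery proportion.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
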
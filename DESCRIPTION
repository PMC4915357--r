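Package: admixwave
Title: Ordering and Dating Multiple Admixture Events from Ancestry
    Components and Local-Ancestry Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the chronology of complex admixture
    histories from genome-wide ancestry data. Implements the admixture
    history graph (AHG), which orders the arrival of K ancestry components
    by testing, for every trio of components, the covariance between a
    candidate recent component and the ratio of the two older ones; a Haar
    wavelet summary of local-ancestry block widths with sequential masking
    of recent ancestry, so that each admixture event can be dated in turn
    against simulation-derived calibration tables; and a forward-in-time
    multi-pulse admixture simulator (tract mosaics under Poisson
    recombination on a genetic map) used for validation and calibration.
    Readers and writers are provided for ADMIXTURE-style Q matrices,
    HapMap-format genetic maps, windowed local-ancestry calls and ancestry
    tract intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
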
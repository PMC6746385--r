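Package: gridcropens
Title: Parameterization Uncertainty in EPIC-Style Gridded Crop Model Ensembles
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale framework for studying parameterization-induced
    uncertainty in ensembles of gridded crop models that share an EPIC-style
    process core. Provides a synthetic gridded agro-environment generator
    (daily weather, layered soils, management, harvested areas, reported
    national yields), a minimal daily crop-soil simulator with a switchboard
    of six setup domains (cultivars, soil data, soil handling, nutrient
    coefficients, hydrologic coefficients, management), area-weighted yield
    aggregation, ensemble agreement metrics (coefficient of variation, mean
    error, pairwise time-series correlation), benchmarking against detrended
    reported yields, a full 2^6 factorial permutation of setup domains with
    per-domain effect attribution, and driver analyses relating ensemble
    disagreement to fertilizer input, climate region and cultivar choice.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
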
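Package: tvgrn
Title: Time-Varying Gene Regulatory Network Inference from Expression Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step identification of time-varying gene regulatory networks
    from short expression time series. Regime switches of a switching vector
    autoregressive model are detected online by monitoring the whiteness of
    the Kalman/recursive-least-squares innovation process with a cumulative
    chi-square statistic; each detected segment is then assigned a static
    directed network by rank-based inner composition alignment (IOTA) scoring
    or per-gene L1-penalised autoregression, and candidate edge rankings can
    be evaluated by AUROC/AUPR against gold-standard edge lists in DREAM
    format. Includes a seeded switching-AR simulator and the benchmark
    designs used to calibrate the detector.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
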
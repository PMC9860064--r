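Package: cocultx
Title: Growth and Mortality Curve Analysis for Phototroph-Heterotroph Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term batch co-culture fluorescence time
    series of marine phototrophs (Prochlorococcus) grown with heterotrophic
    bacteria (Alteromonas). Extracts growth-phase parameters (growth rate, lag,
    peak) by log-linear regression, fits four mortality models (exponential,
    bi-exponential, harmonic, Weibull) to the decline phase by robust
    multi-start bounded least squares, and compares them by RMSE and BIC,
    including Weibull decimal-reduction-time statistics. Converts flow-cytometry
    cell counts to nitrogen biomass through cellular N quotas for carrying
    capacity and synergy (log2 fold change) analysis. Provides peak-aligned,
    daily-gridded, standardized curve matrices for PCA ordination, PERMANOVA,
    and random-forest strain classification, plus a synthetic-data generator
    with known ground truth and a one-command analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
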
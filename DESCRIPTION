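Package: qsarprofiler
Title: Transparent Application of QSA(P)R Models with Uncertainty and
    Applicability-Domain Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Applies user-defined multiple-linear-regression and
    linear-discriminant-analysis quantitative structure-activity
    (property) relationship models to target chemicals and reports
    fully transparent, report-ready tables. Provides leverage-based
    structural applicability domains (Williams plot data), t-based
    prediction intervals, endpoint applicability-domain rules on
    standardized residuals, experimental range and interval range,
    inverse-variance consensus averaging, Shannon-entropy uncertainty
    and cosine-similarity domains for classifiers, fingerprint-based
    neighbor detection (Tanimoto, Dice, cosine), and an XML exchange
    format for model definitions. Chemical structures are handled via
    ChemmineR/ChemmineOB; a small documented descriptor set is computed
    natively and arbitrary descriptors can be supplied as tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    xml2,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
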
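Package: qdbtools
Title: Create, Validate and Use QSAR DataBank Model Archives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with QSAR DataBank (QDB) archives, the
    container format used to exchange quantitative structure-activity
    relationship models together with their compounds, descriptors and
    predictions. Reads and writes the ZIP-based archive layout with XML
    registries and tab-separated value cargos, performs three-level
    archive validation (structural sanity, reusability of identifiers,
    reproducibility of stored predictions), evaluates model equations,
    computes regression and classification summary statistics, derives
    applicability-domain diagnostics (leverage, Mahalanobis distance,
    Williams-plot data, Euclidean nearest neighbours), and provides a
    prediction engine with single and batch modes plus a deterministic
    generator of synthetic archives for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
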
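Package: confmet
Title: Confidence Scoring and False Discovery Rate Estimation for
    Small-Molecule Structure Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding which in-silico structure annotations of
    tandem mass spectra can be trusted. Calibrates raw candidate scores
    into P values and E values with a Gaussian kernel density estimate
    over proxy-decoy scores, combines calibrated scores with further hit
    features in a sign-constrained linear support vector machine whose
    decision values are mapped to posterior estimates by Platt scaling,
    and converts the resulting confidence scores into false discovery
    rate and q-value estimates. Includes exact-FDR bookkeeping, ROC and
    hop-plot evaluation, a spectral noise model for emulating
    biological-quality fragmentation spectra, MGF/MSP input and output,
    spectral cosine matching, molecular structure comparison (Tanimoto,
    exact maximum common edge subgraph distance), and synthetic data
    generators so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
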
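Package: retrodrift
Title: Multistage Cancer-Risk Scaling and Neutral Retrogene Duplication-Drift Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether an expanded tumor-suppressor retrogene
    family reflects adaptive cancer suppression or neutral duplication and
    drift. Implements the evolutionary multistage model of carcinogenesis
    (lifetime risk p = C(ukT)^M) with calibration of the somatic mutation
    rate on a small-bodied reference species and solvers for the added
    driver-mutation count or mutation-rate fold-reduction required by larger,
    longer-lived species, with an optional metabolic-rate scaling of the cell
    division rate; a pure-birth (Yule) duplication-drift model of retrogene
    copy accumulation with a stochastic simulator, log-linear slope fitting
    and a per-generation duplication-rate estimator; and a frameshift-aware
    retrogene ORF-decay analysis that tracks indels against a canonical
    coding sequence, reports frame segments, scrambled spans, truncation
    fractions and Nei-Gojobori dN/dS. A deterministic synthetic-data
    generator emulating the African elephant TP53 retrogene family provides
    all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
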
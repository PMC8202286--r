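Package: pvprobe
Title: Causal Probing of Adverse-Event Report Classifiers for Pharmacovigilance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns structured adverse-event case reports into template
    sentences, fits a probabilistic endpoint classifier (a compact
    self-attention text encoder or a token-logistic baseline), and probes the
    fitted classifier with an interventional do-style procedure: for every
    clinical term the predicted endpoint probabilities are partitioned into
    do/not-do strata and compared with a one-tailed two-sample z-test under
    multiplicity correction, yielding a set of enriched causal terms. Enriched
    terms are organised into a recursive causal tree by re-running the probe
    inside parent-term strata, run-to-run robustness is quantified by
    common-term overlap and percentage-of-overlapped-terms (POT) curves, and
    results are compared head-to-head with classical disproportionality
    statistics (PRR, ROR and the DuMouchel gamma-Poisson EBGM/EB05 shrinker).
    A synthetic case-report generator with planted logistic effects makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
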
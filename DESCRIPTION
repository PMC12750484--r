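Package: bronchoscore
Title: Composite Bronchoscopy Scoring and Chance-Corrected Inter-Rater Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a modified pediatric bronchoscopy scoring tool for
    cystic fibrosis airway disease: ten visual features rated per bronchial
    lobe on ordinal scales are aggregated into per-recording composite scores
    by a threshold-based majority algorithm (maximum-across-lobes for
    secretion color on the Murray sputum chart). Provides a full inter-rater
    reliability engine around the scores: weighted Gwet's AC2 (AC1 as the
    identity-weight special case) with linearized variance and t-based
    confidence intervals, Cohen's weighted kappa for methodological
    comparison, pairwise and stratified coefficients, and Landis-Koch
    interpretation bands. Includes a latent-severity synthetic multi-rater
    study generator with controllable rater noise, bias and marginal
    imbalance, an end-to-end study analysis pipeline with CSV/JSON reports,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
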
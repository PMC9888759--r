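Package: hdrps
Title: Dynamic Picture-Based Affect Scales: Library Screening, Administration
    and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and validating dynamic picture-based affect
    scales. Multi-rater 9-point valence/arousal ratings are screened into an
    affect-labeled picture library via modal-label identity ratios and a
    two-round label-consistency merge; category-stratified picture-choice
    trials are generated and scored into affect scores and labels; and the
    accompanying psychometric battery (Cronbach's alpha, mean item-total
    reliability, concurrent/discriminant validity, paired pre/post tests,
    SAM label consistency, and rMSSD affective-instability analysis) is
    provided together with a synthetic cohort generator with known ground
    truth for end-to-end testing without real photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
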
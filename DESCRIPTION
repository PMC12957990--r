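Package: bothaudit
Title: Resampling Audit of Paired Impairment and Botheredness Ratings
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests whether self-reported impairment ratings on a modified
    Work and Social Adjustment Scale (WSAS) are interchangeable with
    self-reported botheredness ratings. Provides tie-aware Spearman rank
    correlation with a permutation significance test (Monte Carlo and
    exact enumeration), a paired sign-flip randomization test of
    interchangeability with an exact enumeration twin, descriptive
    summaries of ordinal rating distributions, a Gaussian-copula
    generator of paired ordinal questionnaire data with calibrated rank
    correlation and location shift, and simulation tools for type-I
    error and power of both resampling tests. The whole analysis runs as
    a single seeded audit returning per-item and pooled results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
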
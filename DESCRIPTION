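Package: ncdcra
Title: Comparative Risk Assessment of NCD Risk Factor Reductions on Health Expenditure
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic comparative risk assessment (CRA) pipeline linking
    reductions in the prevalence of four noncommunicable-disease risk factors
    (tobacco use, harmful alcohol use, high systolic blood pressure, high blood
    glucose) to savings in projected current health expenditure and to
    reductions in disability-adjusted life years (DALYs) for five conditions
    (cancer, type 2 diabetes, cardiovascular disease, COPD, chronic kidney
    disease) across 24 Latin American and Caribbean countries, 2020-2050.
    Includes validated tabular data types keyed by country, five-year age
    group, ICD-10 chapter and year; a synthetic-data generator emulating the
    joint structure of burden-of-disease and expenditure-projection inputs; a
    multiplicative baseline expenditure projection; the policy-impact engine
    with a ten-year linear phase-in and discounting; and report tables at
    country, region and all-country level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
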
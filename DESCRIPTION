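Package: vaxcarditis
Title: Matched Case-Control Analysis of Myocarditis and Pericarditis Risk
    After mRNA Covid-19 Vaccination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a nationwide matched case-control study of acute
    myocarditis and pericarditis following mRNA Covid-19 vaccination:
    generation of seeded synthetic claims-style registries (persons,
    vaccinations, hospital stays, SARS-CoV-2 tests), ICD-10 case
    ascertainment, 10:1 risk-set matched control sampling within strata of
    sex, age and department of residence, classification of vaccine
    exposure into dose- and delay-specific risk windows, conditional
    logistic regression fitted from scratch by Newton-Raphson on the exact
    conditional likelihood, and vaccine-attributable burden estimation
    (excess cases per 100,000 doses, doses per attributable case) with
    delta-method confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
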
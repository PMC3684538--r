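Package: fpimpact
Title: Modelling a Family Planning Organisation's Contribution to the
    Modern Contraceptive Prevalence Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts a family planning service delivery organisation's
    annual commodity and service counts into modelled numbers of
    contraceptive users, and into the organisation's annual
    percentage-point contribution to increasing the national modern
    contraceptive prevalence rate (CPR), following the level-1
    methodology of Marie Stopes International's Impact 2 model.
    Long-acting methods (IUDs, implants) are tracked as virtual cohorts
    thinned by cumulative continuation rates; sterilisation cohorts are
    thinned by model life-table survival; short-term commodities are
    converted by units-per-year-of-coverage. A client profile (adopters,
    continuers, provider changers) handles client substitution, and
    demographic denominators handle population growth. Includes a
    synthetic-data generator, client-profile sensitivity sweeps, CSV/YAML
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
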
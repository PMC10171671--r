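Package: sodiumcra
Title: Comparative Risk Assessment of Population Sodium Reduction Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the cardiovascular mortality impact of reducing population
    sodium intake. Caps branded-food sodium densities at category benchmark
    targets to simulate reformulation of the food supply, rebuilds age- and
    sex-stratified usual-intake distributions under counterfactual scenarios
    (reformulation or proportional scaling to a population target), and runs a
    PRIME-style comparative risk assessment through the salt -> systolic blood
    pressure -> cause-specific cardiovascular mortality pathway, with Monte
    Carlo uncertainty intervals. Includes a synthetic-data generator emulating
    24-h dietary recall microdata, a branded food supply with benchmark
    targets, and age/sex/cause-stratified mortality tables, so the full
    pipeline runs end to end without restricted-access survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
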
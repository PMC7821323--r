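Package: ipmecon
Title: Bioeconomic Decision Framework for Insect Pest Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expected-value decision analysis for integrated pest management
    (IPM) under uncertain pest outbreaks and insecticide resistance. Computes
    expected yield and expected net revenue for coded management scenarios
    (variety traits, spray policy, scouting, pest resistance status), solves
    break-even probability thresholds in closed form, runs probability sweeps
    and sensitivity analyses, and estimates outbreak frequency and yield loss
    from insecticide-trial site-year records. Ships the 2018 Iowa soybean
    aphid (Aphis glycines) case study as its default configuration and a
    command-line interface for scenario evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
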
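Package: adlshift
Title: Behavior Shift Detection for Ambient Assisted Living Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects shifts from a user's frequent behaviors in smart-home
    event logs. Frequent behaviors (activities of daily living) are modelled
    as Markov chains over discrete actions; an observed episode is scored by
    its likelihood under each chain, and episodes with zero likelihood are
    repaired against every sufficiently likely chain path with a
    Damerau-Levenshtein edit script (insert, delete, substitute, swap).
    Modification sets are weighted by a domain-expert criticality mapping and
    combined into a behavior risk factor that flags anomalous episodes.
    Includes a transition-frequency model learner, a seeded episode simulator
    with controlled perturbation injection, an adapted cross-validation
    harness, and file formats for models, event logs and reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
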
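Package: rrtvalidate
Title: Individual-Level Validation of Randomized Response Techniques
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based prevalence estimation for sensitive survey questions under
    direct questioning and three randomized response technique (RRT) variants
    (crosswise model, unrelated-question, forced-response), with misclassification
    inversion, delta-method and bootstrap variances, and individual-level validation
    of true/false positive rates against observed or latent truth from incentivized
    dice games. Includes a synthetic dice-game survey generator emulating random arm
    allocation, Benford's-law and birthday randomizing devices, and configurable
    honest, lying, confused and self-protective response behavior, so the full
    comparative, aggregate-level and individual-level analysis pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
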
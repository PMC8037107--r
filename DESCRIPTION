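Package: ablatecea
Title: Cost-Effectiveness of Surgery and Thermal Ablation for Colorectal
    Liver Metastases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model comparing surgical
    resection, radiofrequency ablation (RFA) and microwave ablation (MWA)
    for liver metastases of oligometastatic colorectal cancer. Couples a
    30-day short-run treatment model to a four-state annual-cycle Markov
    model (no recurrence, hepatic-only recurrence, any other recurrence,
    death) run to age 100, and computes discounted lifetime costs and
    quality-adjusted life years, dominance and net monetary benefit,
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, and a deterministic starting-age sweep. Includes
    a Gompertz life-table generator, a patient-level microsimulation used
    to cross-check the cohort engine, and a small command-line interface.
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
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
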
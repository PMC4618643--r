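Package: pkcross
Title: Noncompartmental Pharmacokinetics and Crossover Drug-Drug Interaction
    Analysis for IV-Infusion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses phase I crossover studies of intravenously
    infused drugs. Provides closed-form one- and two-compartment infusion
    models with urinary excretion, a seeded generator of study-faithful
    crossover datasets (plasma, urine and dosing records with log-normal
    between- and within-subject variability and LLOQ censoring), a
    noncompartmental analysis engine (linear-up/log-down trapezoidal AUC,
    terminal-slope estimation with reportability gating, clearances,
    accumulation and linearity ratios, geometric summaries), geometric
    least-squares mean ratio estimation with 90% confidence intervals and the
    80-125% no-interaction decision, and analytic and simulated power for the
    two one-sided tests procedure.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
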
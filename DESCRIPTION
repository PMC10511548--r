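Package: fncea
Title: Cost-Effectiveness of G-CSF Prophylaxis for Febrile Neutropenia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid decision-tree/Markov cohort model of primary versus
    secondary granulocyte colony-stimulating factor (G-CSF) prophylaxis of
    chemotherapy-induced febrile neutropenia in breast cancer, non-small cell
    lung cancer and non-Hodgkin lymphoma. Implements a cycle-level
    chemotherapy phase, an annual post-chemotherapy Markov phase with additive
    excess mortality and a 20-year cure assumption, discounted
    cost/life-year/QALY accrual, incremental cost-effectiveness ratios with
    dominance classification, one-way (tornado) and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, a patient-level
    microsimulation oracle, and calibration of unpublished cost inputs
    against published base-case totals. Ships 18 country-by-cancer-by-agent
    scenario fixtures with synthetic parametric life tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
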
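Package: inhpbpk
Title: Whole-Body Physiologically Based Pharmacokinetics of Isoniazid in
    NAT2 Acetylator Phenotypes and Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A whole-body, perfusion-limited physiologically based
    pharmacokinetic (PBPK) model of isoniazid resolved by N-acetyltransferase
    2 (NAT2) acetylator phenotype (fast, intermediate, slow). Derives
    phenotype-specific hepatic and systemic clearance parameters from
    published clearance values, predicts tissue-to-plasma partitioning with
    the Rodgers-Rowland method, simulates virtual populations with seeded
    inter-individual variability, and evaluates simulations against
    drug-specific lognormal acceptance limits and the absolute average fold
    error. Includes a pregnancy physiology model (gestational scaling of
    glomerular filtration, cardiac output, plasma volume and body weight),
    sensitivity analysis of NAT2 versus non-NAT2 clearance pathways during
    pregnancy, therapeutic-window classification, and phenotype-mixture
    population simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
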
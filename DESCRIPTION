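Package: cspdyn
Title: Community Dynamics and Mate Choice Under Reproductive Interference
    with Conspecific Sperm Precedence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study whether two closely related species can coexist
    locally when they interfere with each other's reproduction but exhibit
    conspecific sperm precedence (CSP). Implements a behaviourally explicit
    mating decision-making tree (closed form for two matings, exact dynamic
    programming and a Monte-Carlo simulator for an arbitrary number of
    matings), the resulting expected-fecundity functions and two-species ODE
    community dynamics, equilibrium finding, local stability analysis,
    invasion fitness, the exclusion-stability boundary b + c = 1, and basins
    of attraction with phase-portrait export. Also provides the companion
    behavioural analysis: signal-detection indices (d-prime, beta, criterion),
    binary-decision ROC/AUC, an unpaired DeLong comparison of AUCs, mapping of
    mating-trial session records to contingency counts, a comparative summary
    of CSP species pairs by distribution/niche category, and seeded synthetic
    generators for mating-trial sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
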
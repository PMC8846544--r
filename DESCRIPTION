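Package: adtpsa
Title: Mechanistic Models of PSA Dynamics Under Androgen Deprivation Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and estimation tools for hormone-sensitive prostate
    cancer under androgen deprivation therapy (ADT). Implements a family of
    PSA growth laws including a super-exponential power-of-log law, two
    pharmacokinetic formulations for depot leuprolide (transit-compartment
    mass action and diffusion-limited microsphere release), the
    LHRH/LH/testosterone feedback system with drug competition, a coupled
    tumor-hormone treatment model with two acquired-resistance mechanisms,
    threshold (separatrix) analysis of treatment failure, a nonlinear
    mixed-effects fitter for longitudinal log-PSA data with model-selection
    metrics, and a synthetic-cohort generator emulating sparse registry data.
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
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
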
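Package: percsim
Title: Chemostat Modeling of Perchlorate Inhibition of Sulfate-Reducing Microorganisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates continuous-culture (chemostat) dynamics of
    sulfate-reducing microorganisms (SRM) under perchlorate stress using a
    two-compartment (planktonic and surface-attached) logistic growth model
    whose specific growth rate is modulated by a variable-slope Hill
    dose-response inhibition function. Provides closed-form steady-state and
    washout analytics, nonlinear least-squares fitting of dose-response
    curves from endpoint gradient plates or batch growth rates, a log-log
    calibration regression mapping SRM community fraction to dissolved
    sulfide, and seed-deterministic synthetic data generators for every
    input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
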
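Package: nanorelease
Title: Temperature-Dependent Multi-Mechanism Drug Release Kinetics for
    Biodegradable Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models cumulative drug release from biodegradable polymer
    nanoparticles as a convex combination of mechanistic kernels: a
    first-order initial burst, a Prout-Tompkins (logistic)
    degradation-relaxation stage, and Fickian diffusion out of a sphere
    (Crank series solution). Provides the two-stage burst + relaxation
    (BR) and three-stage burst + relaxation + diffusion (BRD) models,
    Arrhenius temperature laws for every rate parameter with
    activation-energy regression, constrained multistart nonlinear
    least-squares fitting with adjusted R-squared model comparison,
    synthetic release-profile generation with sampling-withdrawal mass
    balance, parametric temperature sweeps, delimited-text profile I/O,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
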
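Package: mpbpkgsa
Title: Global Sensitivity Analysis for Minimal PBPK Models with Correlated Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for global sensitivity analysis (GSA) of minimal
    physiologically based pharmacokinetic (mPBPK) models of orally dosed
    drugs.  Provides truncated normal/lognormal/Weibull parameter marginals
    with AIC-based family selection, Gaussian-copula sampling of correlated
    virtual populations, a four-compartment mPBPK model (systemic blood,
    portal vein, liver, optional single adjusting compartment) with direct
    or Michaelis-Menten hepatic intrinsic clearance, and three GSA engines:
    Morris elementary-effects screening, variance-based Sobol indices for
    independent inputs, and copula-based extended Sobol indices for
    correlated inputs.  Ships configurations for quinidine, alprazolam and
    midazolam and ranks parameter influence on Cmax, Tmax and partial AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    lhs,
    fitdistrplus,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
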
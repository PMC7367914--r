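# mpbpkgsa

Global sensitivity analysis (GSA) for minimal physiologically based
pharmacokinetic (mPBPK) models with correlated parameters.

## The problem

PBPK models of oral drug disposition have many uncertain, inter-correlated
parameters (body weight, hepatic blood flows, enzyme abundances, plasma
binding, tissue partitioning).  Before calibrating such a model one wants to
know **which parameters actually drive the outputs of interest** — the peak
plasma concentration `C_max`, its time `T_max`, and the partial exposures
`AUC_24h` / `AUC_48h`.  Popular GSA methods (Morris screening, Sobol
variance decomposition) assume independent inputs; in a physiologically
realistic virtual population the inputs are *not* independent, and ignoring
that can mis-rank parameter importance.  This package implements, for a
four-compartment mPBPK model (systemic blood, portal vein, liver, optional
single adjusting compartment) of quinidine, alprazolam and midazolam:

* **Truncated parameter marginals** (normal / lognormal / Weibull, with AIC
  selection of the best family from population samples);
* a **Gaussian-copula virtual population** sampler with an estimated,
  significance/magnitude-sparsified correlation matrix;
* three GSA engines:
  * **Morris elementary effects** — `r` one-at-a-time trajectories on an
    `l`-level grid; per parameter `mu* = mean|EE|`, `sigma = sd(EE)`, ranked
    by the global index `GI = sqrt(mu*^2 + sigma^2)`;
  * **Sobol indices** (independent inputs) — first-order
    `S_i = Var(E[Y|X_i])/Var(Y)` (Saltelli 2010 estimator) and total effect
    `S_Ti = E[Var(Y|X_~i)]/Var(Y)` (Jansen estimator) from an
    `N(k+2)`-evaluation design;
  * **extended (copula-based) Sobol indices** for correlated inputs —
    Kucherenko-style conditional sampling in latent-normal space; under
    correlation `S_i,ext` absorbs correlated contributions and may exceed
    `S_Ti,ext` or even 1.

Parameters with `S > 0.01` (1% of output variance) are classed
*influential*, above 0.1 *key*.

The audience is PBPK/pharmacometrics modellers who want a reproducible,
scripted GSA workflow outside a commercial simulator.

## Worked example

```r
library(mpbpkgsa)

qd  <- drug_spec("quinidine")          # printed marginals, dose 200 mg
sim <- simulate_pbpk(qd, central_values(qd))
sim
#> <pbpk_sim> quinidine, analytic solution, t in [0, 48] h
#>   Cmax 0.8866 mg/L at Tmax 1.25 h; AUC24 8.409, AUC48 9.014 mg*h/L

run <- run_gsa("quinidine", "sobol", N = 2000, seed = 1)
head(run$tables$AUC_24h, 5)
#>       parameter      S     ST interaction rank       class
#> 1 CL_int_CYP3A4 0.8084 0.8470     0.03867    1         key
#> 2           f_a 0.1285 0.1193    -0.00916    2         key
#> 3            BW 0.0343 0.0325    -0.00181    3 influential
#> 4          V_ss 0.0351 0.0260    -0.00901    4 influential
#> 5           f_u 0.0196 0.0260     0.00634    5 influential
```

The 200 mg oral dose peaks at 0.89 mg/L around 1.25 h in the median
subject.  The variance decomposition of `AUC_24h` says ~85% of the
population variance in exposure comes from CYP3A4 intrinsic clearance,
~12% from the fraction absorbed, with everything else minor — the two
*key* parameters one would prioritise for calibration.

Correlated analysis and scenarios:

```r
fx <- default_fixture("alprazolam")    # marginals + correlation fixture
ext <- run_gsa(fx$drug, "ext_sobol", N = 2000, seed = 1, corr = fx$corr)
nf  <- run_gsa("alprazolam", "ext_sobol", N = 2000, seed = 1,
               scenario = "normalized_flows")   # flows per kg body weight
val <- validate_gsa()                  # engines vs closed-form benchmarks
```

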
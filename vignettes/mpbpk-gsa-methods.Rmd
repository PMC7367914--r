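---
title: "Methods: global sensitivity analysis of a minimal PBPK model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global sensitivity analysis of a minimal PBPK model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpbpkgsa)
```

## The model

The package simulates oral drug disposition with a minimal PBPK model of
four compartments: systemic blood (volume `V_sys`, L), portal vein blood
(`V_pv`), liver tissue (`V_liver`), and an optional empirical *single
adjusting compartment* (SAC) with first-order transfer rates `K_in`,
`K_out` (1/h) and volume `V_sac` (L/kg body weight).  Absorbed drug enters
the portal vein as a first-order input `f_a k_a F_g Dose e^(-k_a t)`, where
`f_a` is the fraction absorbed, `F_g` the fraction escaping gut-wall
metabolism and `k_a` (1/h) the absorption rate constant.  Liver inflow is
the portal vein flow `Q_PV` plus the hepatic artery flow `Q_HA` (L/h);
hepatic outflow leaves at `C_liver / (Kp_liver / BP)` (well-stirred liver,
partition coefficient `Kp_liver`, blood:plasma ratio `BP`).  Elimination is
hepatic — unbound intrinsic clearance `CL_uintH` acting on
`f_u C_liver / Kp_liver` — plus renal clearance `CL_R` on plasma.

`V_sys` is not sampled directly; it is derived by inverting the
steady-state-volume relation
`V_ss = (Kp_liver V_liver + V_sys BP - V_sac BW) / BW`, i.e.
`V_sys = (V_ss BW - Kp_liver V_liver + V_sac BW) / BP`.  The subtraction
makes physically infeasible combinations possible (`V_sys <= 0`); such
subjects are **rejected and counted**, the run aborts if the rate exceeds
5% for the distribution-sampling engines (for Morris, which deliberately
sweeps rectangular ranges, affected trajectories are dropped and counted
instead, with a warning).  The printed volume relation is inverted exactly
as stated, including the sign of the SAC term; the SAC volume enters the
differential equations as the absolute volume `V_sac * BW` to keep units
consistent with that relation.

Hepatic intrinsic clearance comes in two modes:

* **direct** (quinidine: CYP2E1 + CYP2C9 + CYP3A4; alprazolam: CYP3A4 +
  CYP3A5): the per-enzyme `CL_int` values (L/h) are sampled and summed —
  the ODE system is linear with constant coefficients;
* **Michaelis–Menten** (midazolam: CYP3A4 + CYP3A5 + UGT1A4): each enzyme
  contributes `A_enz * sum_s Vm_s / (Km_s + C_u,liver)` over its metabolic
  sub-pathways (1-OH and 4-OH for the CYPs), with abundance `A_enz` (pmol)
  sampled and `Vm` (pmol/min/pmol), `Km` (µM) fixed.  The unbound liver
  concentration `C_u,liver = f_u C_liver / Kp_liver` is converted from mg/L
  to µM through the molecular weight (midazolam: 325.8 g/mol, a
  configuration value, not a tabulated one), and pmol/min/µM is converted
  to L/h by the factor `6e-5`.  The clearance is re-evaluated continuously
  along the trajectory, so midazolam kinetics are mildly nonlinear.
  *Caveat*: the UGT1A4 `Vm` is tabulated per mg microsomal protein while
  the abundance is in pmol UGT; the same `A*Vm/(Km+Cu)` form is applied, a
  unit inconsistency that cannot be resolved from the source tables and is
  inherited as-is.

Endpoints are computed on the **plasma** concentration `C_sys / BP`:
`C_max` (mg/L), `T_max` (h), and the cumulative partial areas `AUC_24h`,
`AUC_48h` (mg·h/L) carried as an auxiliary integral state.

### Numerics

Direct-clearance drugs form a linear constant-coefficient system; the
default solver is the exact eigendecomposition closed form (modes
`g_j(t) = (e^{lambda_j t} - e^{-k_a t}) / (lambda_j + k_a)`, with series
fallbacks when `lambda_j` approaches `0` or `-k_a`), with `C_max` located
by golden-section refinement of the closed-form curve and closed-form
partial areas.  The numerical route (`method = "ode"`) uses `lsoda` with
the right-hand side compiled in C, relative tolerance `1e-8`, absolute
`1e-10`, a 0.01 h output grid for trajectory work (0.05 h inside the GSA
drivers, where `C_max` is refined by a local quadratic fit and the AUC
states are grid-independent), and a 10 h cap on the internal step so the
dense-output interpolation stays well-conditioned long after the drug has
decayed.  The portal-vein compartment is stiff (`Q_PV / V_pv` is of order
10^4 per hour), which is why a stiff-capable integrator is required.  The
two routes are cross-checked against each other in the test suite, and the
numerically integrated `AUC_inf` is checked against the independent
linear-algebra oracle `-A^{-1} b / k_a` over 100 random subjects (both
agree to well below 0.1%).

## Parameter distributions

Every model parameter carries a truncated marginal: family
`normal(mean, variance)`, `lognormal(mean log, variance of log)`,
`weibull(shape, scale)`, `uniform`, or `fixed`.  The second parameter is a
**variance**, not a standard deviation — this reading makes each tabulated
row's implied central value physiological (body weight median
`exp(4.30) ≈ 74 kg`, portal-vein volume `sd = sqrt(6.4e-7) = 8e-4`, i.e.
exactly a 10% CV of 0.008 L).  Truncation is by CDF renormalisation
(inverse-CDF mapping), never rejection, so stratified uniform designs stay
uniform after transformation, and the truncated quantile/CDF pair is
exactly inverse.  `fit_marginal()` reverses the process: maximum-likelihood
fits of the three families (via `fitdistrplus`), selection by lowest
`AIC = 2k - 2 logL` with `k = 2` throughout; no small-sample correction, as
the intended sample size (2000 subjects) makes AICc indistinguishable.
Likelihoods are untruncated; truncation is applied at sampling time.

One deliberate departure from the source tables: the blood:plasma ratio
`BP` upper bound is encoded as 1.0 rather than the printed 100.  The three
drugs' `BP` means are 0.89/0.84/0.64 with standard deviations below 0.033,
so the bound is irrelevant for every distribution-based computation; but
Morris samples ranges *uniformly*, and a [0.55, 100] range would make `BP`
dominate every screening ranking, contradicting the reported behaviour of
the screening method on these drugs.  We read the printed 100 as 1.00.

## The virtual population (synthetic-data stage)

`sample_population()` draws a standard multivariate normal with a given
latent correlation matrix, maps scores through `pnorm` to uniforms and
through the truncated quantiles to values — a Gaussian copula.  The target
matrix is interpreted as the correlation of the **latent scores**, not of
the transformed values; for the mild skew of these marginals the induced
Pearson correlation differs by less than a few hundredths (the round-trip
tests allow ±0.04 at n = 5000), and the latent-space convention makes the
extended-Sobol conditional sampling exact and shares one dependence model
between population generation and GSA.

No numeric correlation matrix is published for these populations, so
`default_correlation()` is an explicitly **synthetic, user-overridable
fixture** encoding the qualitative structure reported for a
simulator-derived European-Caucasian adult population: `Kp_liver`–`f_u` =
0.9 (a strong-but-not-unit value so the two effects remain separable),
body-weight links `V_liver` 0.6, `Q_HA` 0.5, `Q_PV` 0.4 (hepatic-artery
link deliberately the stronger of the two flows), inter-enzyme
clearance/abundance correlations 0.4, all else zero.  Because these
numbers are a fixture, drug-specific index *values* under correlation are
not reproducible — only directional statements are tested.

`estimate_correlation()` returns pairwise Pearson coefficients with
t-transform p-values; `adjust_correlation()` zeroes entries with `p > 0.05`
or `|r| < 0.1` and restores positive semi-definiteness by alternating
projections (zero-pattern enforcement and eigenvalue clipping with diagonal
renormalisation), which makes the adjustment idempotent.

What the generator does **not** emulate: demographic covariates (age, sex,
renal function) behind the printed marginals, non-linear dependence (the
copula is linear in latent space), and any gut–liver enzyme correlation
(`F_g` is sampled independently).  Passing tests therefore demonstrate
correctness of the machinery on this idealised population, not fidelity to
any particular cohort.

## The three GSA engines

**Morris screening** builds `r` randomised one-at-a-time trajectories on an
`l`-level grid with jump `delta = l / (2(l-1))` (defaults `l = 10`,
`r = 200`; the full-scale setting is `r = 1500`).  Elementary effects are
computed in unit-cube scale so `mu*` is comparable across parameters of
different units; ranking uses `GI = sqrt(mu*^2 + sigma^2)` only — Morris is
a screening method and carries no variance-fraction thresholds.  Morris
uses parameter **ranges only** (no distributions).  By default the ranges
are the raw configuration bounds; `range_quantiles = c(0.001, 0.999)`
instead uses quantiles of the truncated marginals.  The raw bounds are
loose simulator limits for several parameters (portal-vein flow up to
150 L/h, portal-vein volume up to 0.15 L), and uniform screening over them
ranks by bound width rather than population spread; with quantile-trimmed
ranges the Morris top sets coincide with the Sobol top sets for the
direct-clearance drugs, which is the regime in which screening is a useful
cheap proxy for the variance-based engines.  That agreement is what the
test suite asserts.

**Sobol** builds the Saltelli design (`A`, `B`, and the `k` column-swapped
`AB_i` matrices; `N(k+2)` model runs) with a randomised-Latin-hypercube
base stream mapped through the truncated marginal quantiles.  Estimators:
Saltelli-2010 for `S_i`, Jansen for `S_Ti` — chosen for their variance
properties; the source protocol does not name its estimators.  Raw values
are reported unclipped, so small negative estimates remain visible as
Monte-Carlo noise rather than being silently truncated.  Repetitions with
distinct seeds (`n_reps`, full-scale 10) quantify estimator dispersion.

**Extended Sobol** (correlated inputs) uses single-loop
double-randomisation in latent-normal space.  First order: draw `z_i`, draw
two independent conditional complements from the Schur-complement
conditional normal, and estimate `S_i,ext = (E[f f'] - f0^2)/V`; total
effect: draw the complement, draw two conditional `z_i` values, and use the
Jansen-type difference estimator.  Conditional draws are mapped through the
truncated quantiles (no rejection), keeping cost deterministic at `4N`
model runs per parameter.  Under positive correlation `S_i,ext` absorbs
correlated contributions and can exceed `S_Ti,ext` and 1 (for the additive
bivariate Gaussian with `rho = 0.5` the closed forms are `S_1,ext = 0.75`
versus `S_T1,ext = 0.25`, and the first-order indices sum to 1.5); with an
identity matrix both reduce to the standard Sobol indices, which the tests
verify on the Ishigami function.  The first-order estimator has a
substantially larger Monte-Carlo variance than the total-effect one; tests
and the validation suite therefore compare repetition means, mirroring the
repeated-analysis protocol.

`validate_gsa()` packages the engine-vs-closed-form checks (Ishigami and
g-function through Sobol, correlated linear Gaussian through extended
Sobol, exact rank agreement for an additive model through Morris) into a
pass/fail report.

## Ranking, classification, scenarios

Variance-based rankings sort on the total-effect index with first-order
values alongside; a parameter's influence class is taken on the larger of
`S` and `S_T` (strictly `> 0.01` influential, `> 0.1` key).  Two scenario
variants rewire the baseline fixture: `normalized_flows` replaces the two
hepatic flows by per-kg versions (`lognormal(-1.24, 1.44e-2)` and
`lognormal(-0.11, 1.77e-2)` L/h/kg, multiplied back by `BW` inside the
model) and removes the body-weight–flow correlations, which is the point of
the normalisation; `independent_cyps` zeroes the inter-enzyme correlations
and keeps everything else.

## Problem sizes and tolerances in the test suite

Analytic-benchmark recovery runs at `N = 8000` with 10 repetitions
(tolerance ±0.02 on every index); drug-level qualitative checks run at
`N = 2000` with three seeds and majority voting; the Morris–Sobol agreement
check uses `r = 150` / `N = 1500`; engine-equivalence checks under
independence use repetition-based Monte-Carlo standard errors rather than
fixed tolerances.  The closed-form-vs-ODE and oracle checks use 100 random
subjects and 0.1% relative tolerance.  These sizes are chosen so the full
suite exercises every claim at meaningful precision while remaining quick
enough to run routinely.

## Known limitations

* The correlation fixture is synthetic; only directional/qualitative
  conclusions about correlated analyses are supported.
* The copula captures linear (latent-space) dependence only.
* Midazolam's terminal half-life in this model is 3.8–5.3 h — the SAC
  (`K_out = 0.25/h`) dominates the tail, longer than the 1.5–2.5 h
  literature value for the drug itself; partial-AUC completeness arguments
  are therefore checked against the model's own tail kinetics.
* Single oral dose only; no transporters, permeability-limited tissues,
  mechanistic gut model, or drug–drug interactions.
* The UGT1A4 unit inconsistency noted above.
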
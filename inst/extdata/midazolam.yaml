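# Midazolam mPBPK configuration; same schema as quinidine.yaml.
# Hepatic clearance is Michaelis-Menten: per-enzyme abundance (pmol, sampled)
# times fixed Vm (pmol/min/pmol) over (Km + Cu_liver) summed over the 1-OH
# and 4-OH sub-pathways; the single adjusting compartment (SAC) is enabled.
# UGT1A4 Vm is tabulated per mg microsomal protein; the same A*Vm/(Km+Cu)
# form is applied (unit caveat documented in the methods vignette).
name: midazolam
dose_mg: 5.0
molecular_weight: 325.8   # used to convert mg/L to uM for the MM terms
sac_enabled: true
clearance_mode: michaelis_menten
parameters:
  - {name: f_a,            family: weibull,   p1: 8.86,   p2: 0.94,     min: 1.0e-06, max: 1.0,    unit: "-"}
  - {name: k_a,            family: lognormal, p1: 1.05,   p2: 0.09,     min: 1.0e-06, max: 10.0,   unit: "1/h"}
  - {name: F_g,            family: normal,    p1: 0.47,   p2: 0.01,     min: 1.0e-06, max: 1.0,    unit: "-"}
  - {name: BP,             family: normal,    p1: 0.64,   p2: 1.05e-03, min: 0.55,    max: 1.0,    unit: "-"}
  - {name: f_u,            family: lognormal, p1: -3.46,  p2: 1.0e-03,  min: 1.0e-06, max: 1.0,    unit: "-"}
  - {name: Kp_liver,       family: lognormal, p1: -0.21,  p2: 9.6e-03,  min: 1.0e-06, max: 10.0,   unit: "-"}
  - {name: A_CYP3A4,       family: lognormal, p1: 15.84,  p2: 0.26,     min: 1.0e+06, max: 1.0e+08, unit: "pmol"}
  - {name: A_CYP3A5,       family: lognormal, p1: 15.72,  p2: 0.18,     min: 1.0e+06, max: 1.0e+08, unit: "pmol"}
  - {name: A_UGT1A4,       family: lognormal, p1: 14.92,  p2: 0.18,     min: 1.0e+05, max: 1.0e+08, unit: "pmol"}
  - {name: Q_HA,           family: lognormal, p1: 3.05,   p2: 1.44e-02, min: 1.0e-06, max: 50.0,   unit: "L/h"}
  - {name: Q_PV,           family: lognormal, p1: 4.19,   p2: 1.05e-02, min: 1.0e-06, max: 150.0,  unit: "L/h"}
  - {name: BW,             family: lognormal, p1: 4.30,   p2: 3.8e-02,  min: 30.0,    max: 200.0,  unit: "kg"}
  - {name: V_pv,           family: normal,    p1: 0.008,  p2: 6.4e-07,  min: 1.0e-06, max: 0.15,   unit: "L"}
  - {name: V_liver,        family: lognormal, p1: 0.39,   p2: 2.97e-02, min: 0.1,     max: 5.0,    unit: "L"}
  - {name: V_ss,           family: normal,    p1: 0.91,   p2: 4.09e-02, min: 1.0e-06, max: 5.0,    unit: "L/kg"}
  - {name: CL_R,           family: normal,    p1: 0.085,  p2: 4.6e-03,  min: 1.0e-06, max: 5.0,    unit: "L/h"}
fixed:
  - {name: K_in,  value: 0.2,  unit: "1/h"}
  - {name: K_out, value: 0.25, unit: "1/h"}
  - {name: V_sac, value: 0.23, unit: "L/kg"}
pathways:
  - enzyme: CYP3A4
    mode: michaelis_menten
    abundance: A_CYP3A4
    sub:
      - {pathway: 1-OH, vm: 5.23, km: 2.16}
      - {pathway: 4-OH, vm: 5.2,  km: 31.8}
  - enzyme: CYP3A5
    mode: michaelis_menten
    abundance: A_CYP3A5
    sub:
      - {pathway: 1-OH, vm: 19.7, km: 4.16}
      - {pathway: 4-OH, vm: 4.03, km: 34.8}
  - enzyme: UGT1A4
    mode: michaelis_menten
    abundance: A_UGT1A4
    sub:
      - {pathway: glucuronidation, vm: 445.0, km: 40.3}
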
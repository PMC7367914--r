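# Quinidine mPBPK configuration: marginal distribution per model parameter
# (family, p1, p2, truncation min/max).  normal: p1 = mean, p2 = variance;
# lognormal: p1/p2 = mean/variance of log values; weibull: p1 = shape,
# p2 = scale.  BP max encoded as 1.0 (blood:plasma ratio upper bound).
name: quinidine
dose_mg: 200.0
molecular_weight: 324.4
sac_enabled: false
clearance_mode: direct_clint
parameters:
  - {name: f_a,            family: weibull,   p1: 8.86,   p2: 0.94,     min: 1.0e-06, max: 1.0,    unit: "-"}
  - {name: k_a,            family: lognormal, p1: 1.05,   p2: 0.09,     min: 1.0e-06, max: 10.0,   unit: "1/h"}
  - {name: F_g,            family: weibull,   p1: 46.3,   p2: 0.96,     min: 1.0e-06, max: 1.0,    unit: "-"}
  - {name: BP,             family: normal,    p1: 0.89,   p2: 9.64e-05, min: 0.55,    max: 1.0,    unit: "-"}
  - {name: f_u,            family: lognormal, p1: -1.61,  p2: 7.0e-03,  min: 1.0e-06, max: 1.0,    unit: "-"}
  - {name: Kp_liver,       family: normal,    p1: 4.37,   p2: 3.95e-02, min: 1.0e-06, max: 10.0,   unit: "-"}
  - {name: CL_int_CYP2E1,  family: lognormal, p1: 0.47,   p2: 4.23e-01, min: 1.0e-06, max: 100.0,  unit: "L/h"}
  - {name: CL_int_CYP2C9,  family: lognormal, p1: 0.18,   p2: 4.27e-01, min: 1.0e-06, max: 100.0,  unit: "L/h"}
  - {name: CL_int_CYP3A4,  family: lognormal, p1: 4.35,   p2: 2.59e-01, min: 1.0e-06, max: 1000.0, unit: "L/h"}
  - {name: Q_HA,           family: lognormal, p1: 3.05,   p2: 1.44e-02, min: 1.0e-06, max: 50.0,   unit: "L/h"}
  - {name: Q_PV,           family: lognormal, p1: 4.19,   p2: 1.05e-02, min: 1.0e-06, max: 150.0,  unit: "L/h"}
  - {name: BW,             family: lognormal, p1: 4.30,   p2: 3.8e-02,  min: 30.0,    max: 200.0,  unit: "kg"}
  - {name: V_pv,           family: normal,    p1: 0.008,  p2: 6.4e-07,  min: 1.0e-06, max: 0.15,   unit: "L"}
  - {name: V_liver,        family: lognormal, p1: 0.39,   p2: 2.97e-02, min: 0.1,     max: 5.0,    unit: "L"}
  - {name: V_ss,           family: lognormal, p1: 0.63,   p2: 2.83e-02, min: 1.0e-06, max: 5.0,    unit: "L/kg"}
  - {name: CL_R,           family: normal,    p1: 1.95,   p2: 3.8e-02,  min: 1.0e-06, max: 5.0,    unit: "L/h"}
fixed:
  - {name: K_in,  value: 0.0, unit: "1/h"}
  - {name: K_out, value: 0.0, unit: "1/h"}
  - {name: V_sac, value: 0.0, unit: "L/kg"}
pathways:
  - {enzyme: CYP2E1, mode: direct, clint: CL_int_CYP2E1}
  - {enzyme: CYP2C9, mode: direct, clint: CL_int_CYP2C9}
  - {enzyme: CYP3A4, mode: direct, clint: CL_int_CYP3A4}
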
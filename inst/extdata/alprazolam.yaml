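# Alprazolam mPBPK configuration; same schema as quinidine.yaml.
name: alprazolam
dose_mg: 0.5
molecular_weight: 308.8
sac_enabled: false
clearance_mode: direct_clint
parameters:
  - {name: f_a,            family: weibull,   p1: 8.86,   p2: 0.94,     min: 1.0e-06, max: 1.0,    unit: "-"}
  - {name: k_a,            family: lognormal, p1: 1.21,   p2: 0.09,     min: 1.0e-06, max: 10.0,   unit: "1/h"}
  - {name: F_g,            family: weibull,   p1: 512.33, p2: 1.0,      min: 1.0e-06, max: 1.0,    unit: "-"}
  - {name: BP,             family: normal,    p1: 0.84,   p2: 2.05e-04, min: 0.55,    max: 1.0,    unit: "-"}
  - {name: f_u,            family: lognormal, p1: -1.25,  p2: 5.4e-03,  min: 1.0e-06, max: 1.0,    unit: "-"}
  - {name: Kp_liver,       family: lognormal, p1: -0.146, p2: 4.9e-03,  min: 1.0e-06, max: 10.0,   unit: "-"}
  - {name: CL_int_CYP3A4,  family: lognormal, p1: 2.10,   p2: 0.26,     min: 1.0e-06, max: 100.0,  unit: "L/h"}
  - {name: CL_int_CYP3A5,  family: lognormal, p1: 1.58,   p2: 0.18,     min: 1.0e-06, max: 100.0,  unit: "L/h"}
  - {name: Q_HA,           family: lognormal, p1: 3.05,   p2: 1.44e-02, min: 1.0e-06, max: 50.0,   unit: "L/h"}
  - {name: Q_PV,           family: lognormal, p1: 4.19,   p2: 1.05e-02, min: 1.0e-06, max: 150.0,  unit: "L/h"}
  - {name: BW,             family: lognormal, p1: 4.30,   p2: 3.8e-02,  min: 30.0,    max: 200.0,  unit: "kg"}
  - {name: V_pv,           family: normal,    p1: 0.008,  p2: 6.4e-07,  min: 1.0e-06, max: 0.15,   unit: "L"}
  - {name: V_liver,        family: lognormal, p1: 0.39,   p2: 2.97e-02, min: 0.1,     max: 5.0,    unit: "L"}
  - {name: V_ss,           family: normal,    p1: 0.76,   p2: 1.06e-02, min: 1.0e-06, max: 5.0,    unit: "L/kg"}
  - {name: CL_R,           family: normal,    p1: 0.68,   p2: 4.6e-03,  min: 1.0e-06, max: 5.0,    unit: "L/h"}
fixed:
  - {name: K_in,  value: 0.0, unit: "1/h"}
  - {name: K_out, value: 0.0, unit: "1/h"}
  - {name: V_sac, value: 0.0, unit: "L/kg"}
pathways:
  - {enzyme: CYP3A4, mode: direct, clint: CL_int_CYP3A4}
  - {enzyme: CYP3A5, mode: direct, clint: CL_int_CYP3A5}
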
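# Default atezolizumab popPK configuration (version 1).
#
# Typical values are calibrated to the published summary pharmacology of
# atezolizumab: clearance 0.2 L/day, steady-state volume V1 + V2 = 6.9 L,
# terminal half-life about 27 days.  The three constraints do not identify
# all four structural parameters; Q and the V1/V2 split below are fixed so
# that all three are honored simultaneously.  Covariate exponents, omega and
# sigma are calibration defaults (the source phase 1 model's estimates are
# not public); substitute published estimates here if available.
typical:
  CL: 0.200      # L/day
  V1: 3.28       # L
  Q: 0.546       # L/day
  V2: 3.62       # L
reference:
  weight: 77     # kg (overall median)
  albumin: 40    # g/L
  tumor_size: 63 # mm
covariate_effects:
  CL:
    - {covariate: weight, form: power, exponent: 0.75, reference: 77}
    - {covariate: albumin, form: power, exponent: -0.45, reference: 40}
    - {covariate: tumor_size, form: power, exponent: 0.12, reference: 63}
    - {covariate: sex, form: fold, level: female, fold: 0.85}
    - {covariate: ada, form: fold, level: positive, fold: 1.16}
  V1:
    - {covariate: weight, form: power, exponent: 0.55, reference: 77}
    - {covariate: sex, form: fold, level: female, fold: 0.90}
  Q:
    - {covariate: weight, form: power, exponent: 0.75, reference: 77}
  V2:
    - {covariate: weight, form: power, exponent: 0.65, reference: 77}
omega:
  # log-scale SDs; ~25-30% CV on CL/V1 so simulated 90% PIs have spans
  # comparable to published 500-patient simulation summaries
  sd: {CL: 0.25, V1: 0.20, Q: 0.25, V2: 0.20}
  corr:
    - {pair: [CL, V1], value: 0.3}
sigma:
  prop: 0.20     # proportional residual error (fraction)
  add: 0.5       # additive residual error (ug/mL)
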
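# Demonstration population parameters for the warfarin KPD model.
# DEMO — not for clinical use. Physiologically plausible round numbers chosen
# so the package can be exercised and tested without transcribing published
# population estimates; dose recommendations computed from this file carry no
# clinical meaning.
provenance: "DEMO — not for clinical use"

units:
  edk50: mg/h

population:
  tv_cl: 0.2        # L/h, typical clearance at 70 kg / 40 y / CYP2C9 *1/*1
  tv_v: 10.0        # L, typical volume at 70 kg
  gamma: 1.0        # Hill coefficient of the inhibition curve
  emax: 1.0         # maximum degree of inhibition
  inr_max: 20.0     # theoretical maximal INR rise above baseline
  mtt1: 30.0        # h, mean transit time, fast chain
  mtt2: 110.0       # h, mean transit time, slow chain
  n_transit: 3
  edk50_by_vkorc1:  # mg/h; A-allele carriers are more warfarin sensitive
    "G/G": 3.0
    "A/G": 2.3
    "A/A": 1.6

covariate_relations:
  reference_weight: 70      # kg
  cl_weight_exponent: 0.75  # allometric exponent on CL
  v_weight_exponent: 1.0    # allometric exponent on V
  reference_age: 40         # years
  cl_age_slope: -0.005      # CL multiplier exp(slope * (age - reference_age))
  cl_cyp2c9:                # clearance multipliers by genotype
    "*1/*1": 1.00
    "*1/*2": 0.85
    "*1/*3": 0.70
    "*2/*2": 0.65
    "*2/*3": 0.50
    "*3/*3": 0.35

random_effects:
  omega_k10: 0.09     # variance of log-scale BSV on k10 (SD 0.3)
  omega_edk50: 0.16   # variance of log-scale BSV on EDK50 (SD 0.4)

residual:
  model: additive
  sigma: 0.15         # additive residual SD on the INR scale
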
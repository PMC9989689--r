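# Average healthy population parameterization of the glucose-insulin model.
# config_version bumps whenever a value changes so that fit results can be
# traced back to the parameter set they were obtained under.
config_version: 1
constants:
  sigma_shape: 1.34        # gastric-emptying Weibull shape (-)
  K_M: 13.2                # Michaelis constant, glucose uptake (mmol/L)
  G_th_ren: 9.0            # renal glucose threshold (mmol/L)
  c1_ren: 0.1              # renal clearance coefficient (L/min)
  V_G: 0.24285714          # glucose distribution volume (L/kg), 17 L / 70 kg
  V_I: 0.18571429          # insulin distribution volume (L/kg), 13 L / 70 kg
  beta_conv: 1.0           # insulin unit-conversion factor (-)
  tau_i: 31.0              # integral time constant (min)
  tau_d: 3.0               # derivative time constant (min)
  f_conv: 0.005551         # glucose mg -> mmol conversion (mmol/mg)
  M_b: 70.0                # body mass (kg)
parameters:
  k1: 0.0105               # gastric-emptying rate (1/min)
  k2: 0.28                 # gut glucose absorption rate (1/min)
  k3: 0.00607              # EGP suppression by plasma glucose (1/min)
  k4: 0.000235             # EGP suppression by interstitial insulin (mmol/L/min per mU/L)
  k5: 0.0424               # insulin-dependent glucose uptake (mmol/L/min per mU/L)
  k6: 2.2975               # secretion, proportional glucose term (mU/L/min per mmol/L)
  k7: 1.15                 # secretion, integral glucose term (mU/L/min per mmol.min/L, /tau_i)
  k8: 7.27                 # secretion, derivative glucose term (mU/L per mmol/L, /tau_d)
  k9: 0.0383               # insulin transfer plasma -> interstitium (1/min)
  k10: 0.284               # interstitial insulin degradation (1/min)
  k11: 0.003               # EGP stimulation by plasma AA (mmol/L/min per mmol/L)
  k12: 3.0                 # secretion response to dAA/dt (mU/L per mmol/L)
  k13: 0.5                 # secretion, proportional AA term (mU/L/min per mmol/L)
  g_b_liv: 0.043           # basal endogenous glucose production (mmol/L/min)
basal:
  G_b_pl: 5.0              # basal plasma glucose (mmol/L)
  I_b_pl: 8.0              # basal plasma insulin (mU/L)
  AA_b_pl: 2.5             # basal plasma total AA (mmol/L)
solver:
  rtol: 1.0e-6
  atol: 1.0e-8
  method: lsoda
  clamp_nonneg: false
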
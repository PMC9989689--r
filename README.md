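# edesprot

Postprandial glucose–insulin dynamics with amino-acid effects.

## What this is for

Classical whole-body glucose homeostasis models describe the response to
an oral *glucose* challenge well, but meals containing protein perturb
glucose metabolism through routes those models omit: circulating amino
acids (AAs) stimulate pancreatic insulin secretion and raise hepatic
glucose output. `edesprot` implements a physiology-based ODE model of
the glucose–insulin system extended with both effects — the E-DES-PROT
model — for researchers in quantitative nutrition and metabolic
physiology who want to fit postprandial glucose/insulin time series from
AA, protein, or dairy challenges and interpret the underlying fluxes.

The model has five states (gut glucose mass, plasma glucose, plasma
insulin, an interstitial insulin signal, and the running glucose
excursion integral). The measured plasma AA concentration enters as a
shape-preserving cubic Hermite forcing function AA(t). The two extended
fluxes are

```
g_liv  = g_b_liv − k3 (G − G_b) − k4 β I_if + k11 (AA(t) − AA_b)

i_pnc  = β⁻¹ [ k6 (G − G_b) + (k7/τ_i) ∫(G − G_b) dt + (k7/τ_i) G_b
             + (k8/τ_d) dG/dt + k12 dAA/dt + k13 (AA(t) − AA_b) ]
```

so `k11 = k12 = k13 = 0` reduces exactly to the base glucose-only model
(verified in the tests against an independently coded base-model
simulator). Calibration minimizes the pooled weighted SSR
`Σ (γ (y − d))²` with γ = 1 for glucose (mmol/L) and γ = 0.1 for
insulin (mU/L), using multi-start bound-constrained Levenberg–Marquardt;
model variants are compared with `AIC = N ln(SSR/N) + 2K` and
`BIC = N ln(SSR/N) + K ln N`; identifiability is assessed by profile
likelihood. A synthetic meal-challenge generator reproduces the sampling
designs of free-AA (0–150 min) and protein/dairy (0–300 min) studies so
the whole pipeline is exercisable without access-restricted clinical
data.

## Worked example

Fit the AA parameters to a synthetic amino-acid challenge (no glucose
dose), inspect the fluxes, and profile a parameter:

```r
library(edesprot)

design <- synthetic_design("AA_ONLY", seed = 7,
                           true_params = population_params(k11 = 0.0045,
                                                           k12 = 2,
                                                           k13 = 0.7))
ds <- generate_dataset(design)
sc <- scenario_config("EDES_PROT", c("k11", "k12", "k13"),
                      n_starts = 5, seed = 1)
fit <- fit_dataset(ds, sc)
fit
#> <edes_fit> EDES_PROT on 'synthetic_AA_ONLY_seed7': SSR = 0.252485 (N = 28, K = 3), AIC = -125.8, BIC = -121.8
#>   estimates: k11 = 0.004786, k12 = 2.159, k13 = 0.7019

fx <- compute_fluxes(fit$trajectory)
max(fx$endogenous_glucose_production)
#> [1] 0.05089  # mmol/L/min, vs basal g_b_liv = 0.043

profile_likelihood(fit, "k13", range = c(0.1, 10), n_grid = 9)
#> <profile_result> k13: optimum 0.7019 (cost 0.25248), 10 grid points, threshold 0.0388
#>   classification: identifiable
```

The fit recovers the generating values (k11 within 7%, k13 within 1%)
from data carrying realistic assay noise; the EGP flux rises above its
basal value while AAs are elevated, the signature of a protein-only
meal. A dataset read from CSV (`read_dataset()`, columns `time_min`,
`glucose_mmol_L`, `insulin_mU_L`, plus one or more AA columns) drops
into the same workflow, and `run_pipeline()` / the
`inst/scripts/edesprot.R` command-line script chain fitting, base-model
comparison, and flux export end to end.

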
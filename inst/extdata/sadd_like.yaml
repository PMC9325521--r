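# Synthetic two-arm cost-utility trial preset emulating the structure of a
# 9-month antidepressants-in-dementia trial: arm sizes, outcome moments and
# missingness margins as reported for that study. All values are synthetic
# generating parameters, not trial data.
"n": [111, 108]
times: [0.0, 0.25, 0.75]
utility_mean:
  - [0.679, 0.733, 0.734]   # control (placebo-like)
  - [0.679, 0.763, 0.827]   # intervention
utility_sd:
  - [0.280, 0.277, 0.237]
  - [0.280, 0.277, 0.237]
cost_mean:
  - [1355, 1437, 2146]
  - [1355, 1130, 2550]
cost_sd:
  - [2748, 3338, 4401]
  - [2748, 1868, 4288]
cost_dist: lognormal
utility_corr: 0.5
cost_corr: 0.4
cross_corr: -0.2
missingness:
  mechanism: MAR_prev_outcome
  p_u: [0.32, 0.47]     # marginal missingness of follow-up utilities
  p_c: [0.155, 0.26]    # marginal missingness of follow-up costs
  gamma_u: -4.0         # lower previous utility -> more missingness
  gamma_c: 1.5          # higher previous cost  -> more missingness
  tau: 5.0              # shared participant frailty (clusters patterns)
seed: 1
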
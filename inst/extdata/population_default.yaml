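indication:
- code: S832
  prev_service: 0.45
  prev_control: 0.045
- code: M942
  prev_service: 0.35
  prev_control: 0.035
- code: M224
  prev_service: 0.3
  prev_control: 0.03
- code: M171
  prev_service: 0.25
  prev_control: 0.025
- code: M232
  prev_service: 0.2
  prev_control: 0.02
- code: M233
  prev_service: 0.15
  prev_control: 0.015
- code: M239
  prev_service: 0.12
  prev_control: 0.012
- code: M255
  prev_service: 0.1
  prev_control: 0.01
- code: M170
  prev_service: 0.08
  prev_control: 0.008
- code: S836
  prev_service: 0.06
  prev_control: 0.006
background:
- code: I10
  prev: 0.35
- code: E785
  prev: 0.3
- code: E119
  prev: 0.22
- code: I251
  prev: 0.15
- code: N179
  prev: 0.05
- code: J449
  prev: 0.12
- code: F329
  prev: 0.1
- code: G473
  prev: 0.08
- code: K219
  prev: 0.14
- code: M810
  prev: 0.07
- code: D649
  prev: 0.06
- code: E039
  prev: 0.11
- code: I489
  prev: 0.09
- code: N183
  prev: 0.04
- code: H409
  prev: 0.05
- code: L309
  prev: 0.03
- code: M545
  prev: 0.2
- code: R600
  prev: 0.06
- code: E669
  prev: 0.13
- code: I341
  prev: 0.02
confounder:
- code: Z794
  base_prev: 0.15
  beta_age: 0.5
  beta_sexF: 0.0
  beta_ndx: 0.8
- code: I509
  base_prev: 0.1
  beta_age: 0.9
  beta_sexF: 0.1
  beta_ndx: 0.7
- code: N390
  base_prev: 0.12
  beta_age: 0.6
  beta_sexF: 0.7
  beta_ndx: 0.5
- code: R296
  base_prev: 0.08
  beta_age: 0.8
  beta_sexF: 0.2
  beta_ndx: 0.9
service_rate: 0.15
n_claims: 50000
setting: carrier
service_code: '29877'
svc_beta_age: 0.3
svc_beta_sexF: -0.2
svc_beta_ndx: 0.3
sex_ratio_f: 0.55
age_p_under65: 0.09
age_shape: 2.0
age_scale: 5.0
dx_nb_size: 3.0
dx_nb_mu: 7.0
dx_max: 25
n_filler: 240
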
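split: SPLIT_80_20
sort: RND
seed: 1
'N': 20
precision: DFPP
digits: ~
summation: NAIVE
dt: '0.01'
duration: 500.0
record_stride: 10
initial_conditions:
  V: '0'
  'n': '0.3'
  a: '0'
  s: '1'
params:
  C: '1'
  g_l: '0.1'
  V_l: '-10.6'
  g_Na: '36'
  V_Na: '115'
  g_K: '12'
  V_K: '-12'
  gbar_syn: '3.6'
  V_exc: '70'
  V_inh: '70'
  alpha_a: '1'
  beta_a: '0.1'
  alpha_s: '0.0015'
  beta_s: '0.12'
  V_th: '40'
  k_v: '6.5'
iapp: ~
unified_accumulation: no
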
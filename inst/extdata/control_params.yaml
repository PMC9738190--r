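format_version: 1
units_note: concentrations uM, times s, rates 1/s, Vmax uM/s, Km uM
supply:
  bHT: 100.0
  V_HTL: 4.0
  K_HTL: 100.0
  k_pool_in: 0.1
  k_pool_out: 0.05
synthesis:
  V_HTDC: 3.0
  K_HTDC: 50.0
  k_cht_loss: 0.02
packaging:
  V_MAT: 1.5
  K_MAT: 2.0
release:
  k_rel: 0.005
  f0: 1.0
  f_stim: 6.5
clearance:
  V_HAT: 4.040114722789
  K_HAT: 10.0
  K_HAT_gi: 10.0
metabolism:
  V_HNMT_g: 3.0
  K_HNMT_g: 10.0
  V_HNMT_c: 1.2
  K_HNMT_c: 10.0
autoreceptor:
  k_on: 0.2
  k_off: 2.0
  k_Gact: 4.0
  k_Gdeact: 20.0
  k_Tact: 1.0
  k_Tdeact: 2.0
  alpha: 0.9
  gstar_eq: 0.329381696427
retrograde:
  s_strength: 0.8
  s_window:
  - 9.0
  - 15.0
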
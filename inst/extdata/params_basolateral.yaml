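k_ATPase: 0.36
k_ADPase: 0.0
Vmax_AMPase: 0.1
Km_AMPase: 14.0
Ftr_AK: 0.4
k1: 1.0
k_minus2: 1.0
K_AK_half: 6.0
Keq_AK: 0.44
Vmax_NDPK: 2.5
Km_AD: 50.0
Km_AT: 170.0
Km_NTP:
  UTP: 100.0
  CTP: 100.0
  GTP: 100.0
Ki_NDP: 300.0
Ki_ADP: 100.0
Keq_NDPK: 1.0
k_NTPase:
  UTP: 0.01
  CTP: 0.0
  GTP: 0.01
J_leakage: 0.004
A_NL:
  '300': 0.02
  '180': 1.0
  '150': 2.0
  '100': 3.0
k_obs: 0.5
k_L: 0.1
M_cell: 0.2
.provenance:
  k_ATPase: literature
  k_ADPase: literature
  Vmax_AMPase: literature
  Km_AMPase: literature
  Km_AT: literature
  Keq_NDPK: literature
  Ki_NDP: literature
  Ki_ADP: literature
  Ftr_AK: fitted
  k1: fitted
  k_minus2: fitted
  K_AK_half: fitted
  Vmax_NDPK: fitted
  Km_AD: fitted
  Km_NTP: fitted
  k_NTPase: fitted
  J_leakage: fitted
  A_NL: fitted
  k_obs: fitted
  k_L: fitted
  M_cell: default
  Keq_AK: literature
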
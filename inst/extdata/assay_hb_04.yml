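pretreatment: HB
loading_pct: 4.0
C0: 24.428
L0: 12.788
Xn0: 0.84
E1T: 0.42
E2T: 0.1017
E3: 5.853
adsorption:
  emax_a: 3.607
  emax_b: -0.00719
  emax_c: -7.72e-05
  kp_a: 0.2501
  kp_b: 0.00134
  kp_c: -0.000146
  emaxL: 0.0
  kpL: 0.0
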
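pretreatment: HB
loading_pct: 10.0
C0: 61.07
L0: 31.97
Xn0: 2.1
E1T: 1.049
E2T: 0.2543
E3: 14.632
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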
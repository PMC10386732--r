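pretreatment: OB
loading_pct: 4.0
C0: 34.8
L0: 2.64
Xn0: 1.768
E1T: 0.42
E2T: 0.1017
E3: 5.853
adsorption:
  emax_a: 3.383
  emax_b: -0.0027
  emax_c: 3.0e-06
  kp_a: 1.008
  kp_b: -0.014
  kp_c: 8.0e-05
  emaxL: 0.0
  kpL: 0.0
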
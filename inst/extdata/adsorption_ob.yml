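pretreatment: OB
emax_a: 3.383
emax_b: -0.0027
emax_c: 3.0e-06
kp_a: 1.008
kp_b: -0.014
kp_c: 8.0e-05
emaxL: 0.0
kpL: 0.0
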
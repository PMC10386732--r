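pretreatment: HB
k1r: 19.178
k2r: 196.56
k3r: 8.576
K1iG2: 0.769
K1iG: 0.03
K1iX: 31.92
K2iG: 14.853
K2m: 22.48
K2iX: 278.2
K3iG2: 0.913
K3iG: 0.853
K3iX: 86.38
k4: 18.066
Keq: 0.0786
K4iX: 0.0111
kS: 0.0354
lambda:
  mode: lignin_hill
  lambda_max: 0.1817
  'n': 9.45
  k: 18.354
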
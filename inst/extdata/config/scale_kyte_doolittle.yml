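# Kyte-Doolittle hydropathy, min-max normalized to [0,1] via (v + 4.5) / 9.
# Higher values = more hydrophobic = more order-prone.
name: kyte_doolittle_normalized
higher_means: order
declared_range: [0.0, 1.0]
values:
  "A": 0.7
  "R": 0.0
  "N": 0.1111111111111111
  "D": 0.1111111111111111
  "C": 0.7777777777777778
  "Q": 0.1111111111111111
  "E": 0.1111111111111111
  "G": 0.4555555555555555
  "H": 0.14444444444444443
  "I": 1.0
  "L": 0.9222222222222223
  "K": 0.06666666666666668
  "M": 0.7111111111111111
  "F": 0.8111111111111111
  "P": 0.3222222222222222
  "S": 0.41111111111111115
  "T": 0.4222222222222222
  "W": 0.4
  "Y": 0.35555555555555557
  "V": 0.9666666666666666
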
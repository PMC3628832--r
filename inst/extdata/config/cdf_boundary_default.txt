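# Default order/disorder CDF boundary: lines "threshold boundary_fraction".
# A monotone diagonal boundary (package default; replace with a
# predictor-calibrated boundary via --boundary or cdf_boundary()).
0.1 0.18
0.2 0.26
0.3 0.34
0.4 0.42
0.5 0.50
0.6 0.58
0.7 0.66
0.8 0.74
0.9 0.82
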
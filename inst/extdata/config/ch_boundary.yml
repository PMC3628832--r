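# Charge-hydropathy boundary line: a protein is on the natively-unfolded
# side when |<R>| > slope * <H> - intercept, with <H> the mean normalized
# Kyte-Doolittle hydropathy and <R> the mean net charge per residue.
slope: 2.785
intercept: 1.151
hydropathy_scale: scale_kyte_doolittle.yml
charge:
  "D": -1
  "E": -1
  "K": 1
  "R": 1
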
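# TKTL1 European-only sensitivity design: 10 noncarriers per carrier,
# exact on sex, age and PC1/PC2 calipers of 2.5.
ratio: 10
exact_on: [sex]
age_caliper: 2.5
pc_calipers:
  PC1: 2.5
  PC2: 2.5
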
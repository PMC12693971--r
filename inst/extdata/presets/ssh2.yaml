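# SSH2 design: 2079 unique noncarriers per carrier, exact on sex and the
# strict ancestry label, age caliper 2.5 years.
ratio: 2079
exact_on: [sex, strict_label]
age_caliper: 2.5
pc_calipers: null
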
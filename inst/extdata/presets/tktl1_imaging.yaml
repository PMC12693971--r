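# TKTL1 imaging design: 429 noncarriers per carrier, matched by age and
# sex only, across ancestries.
ratio: 429
exact_on: [sex]
age_caliper: 2.5
pc_calipers: null
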
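# Example scenario: top-and-bottom genotyping of the C reference population,
# desk scale, with a year-10 variance-component snapshot.
profile: desk
c_strategy: T1_2B1_2
b_strategy: Top1_1
r_g: 0.2
h2: 0.3
prop_C: 0.2
prop_females_kept: 1.0
years: 12
reml_year: 10
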
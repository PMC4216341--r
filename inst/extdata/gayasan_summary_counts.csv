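quantity,numerator,denominator,printed_pct
flora_coverage,200,542,36.9
rosaceae_species_share,13,200,6.5
male_informants,28,208,13.5
oral_administration,NA,NA,84.8
topical_administration,NA,NA,15.2
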
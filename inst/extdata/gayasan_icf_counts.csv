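category,nt,nur,icf_printed
Muscular-skeletal disorders,49,2142,0.98
Pains,87,2942,0.97
Respiratory system disorders,46,1513,0.97
Liver complaints,15,447,0.97
Cuts and wounds,20,473,0.96
Inflammation,28,587,0.95
Genitourinary system disorders,52,1062,0.95
Circulatory system disorders,65,1250,0.95
Skin diseases and disorders,25,464,0.95
Gastrointestinal disorders,68,1257,0.95
Diabetes,10,165,0.95
Nervous system disorders,34,545,0.94
Veterinary ailments,22,300,0.93
Poisonings,26,321,0.92
Others,36,431,0.92
Birth-related disorders,14,138,0.91
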
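species,ailment,fl_printed
Achyranthes japonica (Miq.) Nakai,Arm pain,16.71
Achyranthes japonica (Miq.) Nakai,Arthritis,1.62
Achyranthes japonica (Miq.) Nakai,Bone diseases,32.61
Achyranthes japonica (Miq.) Nakai,Common cold,2.43
Achyranthes japonica (Miq.) Nakai,Convulsion,3.23
Achyranthes japonica (Miq.) Nakai,Knee pain,2.16
Achyranthes japonica (Miq.) Nakai,Leg pain,31.54
Achyranthes japonica (Miq.) Nakai,Lumbago,9.16
Achyranthes japonica (Miq.) Nakai,Pollakiuria,0.54
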
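ailment,category
Arm pain,Pains
Knee pain,Pains
Leg pain,Pains
Shoulder pain,Pains
Finger pain,Pains
Abdominal pain,Pains
Lumbago,Pains
Headache,Pains
Arthritis,Muscular-skeletal disorders
Bone diseases,Muscular-skeletal disorders
Sinews and joint pain,Muscular-skeletal disorders
Carpal tunnel syndrome,Muscular-skeletal disorders
Tarsal tunnel syndrome,Muscular-skeletal disorders
Chronic myofascial pain,Muscular-skeletal disorders
Fracture,Muscular-skeletal disorders
Common cold,Respiratory system disorders
Cough,Respiratory system disorders
Asthma,Respiratory system disorders
Bronchitis,Respiratory system disorders
Jaundice,Liver complaints
Liver diseases,Liver complaints
Hepatitis,Liver complaints
Cut,Cuts and wounds
Bruise,Cuts and wounds
Burns,Cuts and wounds
Pus,Inflammation
Boil,Inflammation
Gastritis,Inflammation
Pollakiuria,Genitourinary system disorders
Hemorrhoids,Genitourinary system disorders
Sterility,Genitourinary system disorders
Woman diseases,Genitourinary system disorders
Leukorrhea,Genitourinary system disorders
Irregular menstruation,Genitourinary system disorders
Hypertension,Circulatory system disorders
Raynaud's Phenomenon,Circulatory system disorders
Paralysis,Circulatory system disorders
Hemorrhaging,Circulatory system disorders
Skin diseases,Skin diseases and disorders
Pruritus,Skin diseases and disorders
Eczema,Skin diseases and disorders
Indigestion,Gastrointestinal disorders
Gastric ulcer,Gastrointestinal disorders
Gastroenteric disorder,Gastrointestinal disorders
Diarrhea,Gastrointestinal disorders
Constipation,Gastrointestinal disorders
Diabetes,Diabetes
Convulsion,Nervous system disorders
Facial nerve paralysis,Nervous system disorders
Neuralgia,Nervous system disorders
Cattle disease,Veterinary ailments
Bovine diarrhea,Veterinary ailments
Pig ailments,Veterinary ailments
Poisoning,Poisonings
Food poisoning,Poisonings
Hookworm,Poisonings
Fatigue,Others
Lack of energy,Others
Hypofunction,Others
Anorexia,Others
Cancer,Others
Eye disease,Others
Edema,Others
Hyperthermia,Others
Overheating,Others
Sexual enhancement,Others
Dysmenorrhea,Birth-related disorders
Afterpain,Birth-related disorders
Abdominal cold hypersentivity,Birth-related disorders
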
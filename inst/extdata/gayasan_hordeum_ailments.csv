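species,ailment,fl_printed
Hordeum vulgare var. hexastichon (L.) Asch.,Abdominal pain,0.62
Hordeum vulgare var. hexastichon (L.) Asch.,Arm pain,6.69
Hordeum vulgare var. hexastichon (L.) Asch.,Arthritis,1.87
Hordeum vulgare var. hexastichon (L.) Asch.,Bone diseases,29.70
Hordeum vulgare var. hexastichon (L.) Asch.,Cancer,0.47
Hordeum vulgare var. hexastichon (L.) Asch.,Carpal tunnel syndrome,1.09
Hordeum vulgare var. hexastichon (L.) Asch.,Chronic myofascial pain,1.09
Hordeum vulgare var. hexastichon (L.) Asch.,Common cold,0.78
Hordeum vulgare var. hexastichon (L.) Asch.,Cough,1.87
Hordeum vulgare var. hexastichon (L.) Asch.,Edema,1.87
Hordeum vulgare var. hexastichon (L.) Asch.,Eye disease,0.78
Hordeum vulgare var. hexastichon (L.) Asch.,Fatigue,1.09
Hordeum vulgare var. hexastichon (L.) Asch.,Finger pain,1.24
Hordeum vulgare var. hexastichon (L.) Asch.,Gastric ulcer,0.16
Hordeum vulgare var. hexastichon (L.) Asch.,Gastritis,0.16
Hordeum vulgare var. hexastichon (L.) Asch.,Gastroenteric disorder,3.73
Hordeum vulgare var. hexastichon (L.) Asch.,Hemorrhaging,0.78
Hordeum vulgare var. hexastichon (L.) Asch.,Hookworm,0.47
Hordeum vulgare var. hexastichon (L.) Asch.,Hyperthermia,0.16
Hordeum vulgare var. hexastichon (L.) Asch.,Hypofunction,1.87
Hordeum vulgare var. hexastichon (L.) Asch.,Indigestion,4.98
Hordeum vulgare var. hexastichon (L.) Asch.,Jaundice,2.33
Hordeum vulgare var. hexastichon (L.) Asch.,Leg pain,14.46
Hordeum vulgare var. hexastichon (L.) Asch.,Liver diseases,1.24
Hordeum vulgare var. hexastichon (L.) Asch.,Lumbago,6.22
Hordeum vulgare var. hexastichon (L.) Asch.,Paralysis,4.82
Hordeum vulgare var. hexastichon (L.) Asch.,Pollakiuria,1.09
Hordeum vulgare var. hexastichon (L.) Asch.,Pruritus,1.71
Hordeum vulgare var. hexastichon (L.) Asch.,Pus,1.87
Hordeum vulgare var. hexastichon (L.) Asch.,Raynaud's Phenomenon,0.31
Hordeum vulgare var. hexastichon (L.) Asch.,Sexual enhancement,0.31
Hordeum vulgare var. hexastichon (L.) Asch.,Shoulder pain,1.56
Hordeum vulgare var. hexastichon (L.) Asch.,Sinews and joint pain,0.16
Hordeum vulgare var. hexastichon (L.) Asch.,Skin diseases,0.93
Hordeum vulgare var. hexastichon (L.) Asch.,Tarsal tunnel syndrome,1.09
Hordeum vulgare var. hexastichon (L.) Asch.,Woman diseases,0.47
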
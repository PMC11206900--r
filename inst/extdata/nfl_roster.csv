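position,body_mass_kg,body_fat_fraction,activity_factor,energy_kcal_day,protein_override_g_day
Defensive Lineman,134.7,,,6250,
Offensive Lineman,144.0,,,6350,
Running Back,110.5,,,5850,
Tight End,123.3,,,6150,
Linebacker,108.1,,,6050,223
Quarterback,100.9,,,5300,219
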
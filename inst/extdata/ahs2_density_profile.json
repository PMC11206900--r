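{
  "reference_energy_kcal": 2000,
  "provenance_note": "Mean nutrient intakes per 2000 kcal/day in the completely plant-based (vegan) stratum of the Adventist Health Study 2 (foods, beverages and supplements summed). Fiber stored at 46.7 g (cohort mean), not the display-rounded 47. Iron, zinc and linoleic acid are stored at display precision (32, 16, 20); the unrounded cohort densities behind them were not published.",
  "entries": [
    {"nutrient": "saturated_fat", "amount": 5.2,  "unit": "% kcal",  "basis": "percent_of_energy"},
    {"nutrient": "protein",       "amount": 14.5, "unit": "% kcal",  "basis": "percent_of_energy"},
    {"nutrient": "total_omega_3", "amount": 2,    "unit": "g",       "basis": "per_reference_energy"},
    {"nutrient": "linoleic_acid", "amount": 20,   "unit": "g",       "basis": "per_reference_energy"},
    {"nutrient": "fiber",         "amount": 46.7, "unit": "g",       "basis": "per_reference_energy"},
    {"nutrient": "vitamin_a",     "amount": 1108, "unit": "mcg RAE", "basis": "per_reference_energy"},
    {"nutrient": "vitamin_b6",    "amount": 14.4, "unit": "mg",      "basis": "per_reference_energy"},
    {"nutrient": "folate",        "amount": 888,  "unit": "mcg",     "basis": "per_reference_energy"},
    {"nutrient": "vitamin_b12",   "amount": 23.3, "unit": "mcg",     "basis": "per_reference_energy"},
    {"nutrient": "vitamin_c",     "amount": 531,  "unit": "mg",      "basis": "per_reference_energy"},
    {"nutrient": "vitamin_d",     "amount": 252,  "unit": "IU",      "basis": "per_reference_energy"},
    {"nutrient": "vitamin_e",     "amount": 101,  "unit": "mg",      "basis": "per_reference_energy"},
    {"nutrient": "calcium",       "amount": 1156, "unit": "mg",      "basis": "per_reference_energy"},
    {"nutrient": "iron",          "amount": 32,   "unit": "mg",      "basis": "per_reference_energy"},
    {"nutrient": "magnesium",     "amount": 652,  "unit": "mg",      "basis": "per_reference_energy"},
    {"nutrient": "phosphorus",    "amount": 1371, "unit": "mg",      "basis": "per_reference_energy"},
    {"nutrient": "potassium",     "amount": 4234, "unit": "mg",      "basis": "per_reference_energy"},
    {"nutrient": "sodium",        "amount": 3531, "unit": "mg",      "basis": "per_reference_energy"},
    {"nutrient": "zinc",          "amount": 16,   "unit": "mg",      "basis": "per_reference_energy"}
  ]
}
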
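nutrient,target_value,target_type,ul_value,unit,caveat
saturated_fat,10,DGA_limit,10,% kcal,
total_omega_3,1.6,AI,ND,g,
linoleic_acid,17,AI,ND,g,
fiber,14,DGA_rate,ND,g,Target of 14 g per 1000 kcal; resolved at the diet's energy level
vitamin_a,900,RDA,ND,mcg RAE,UL is established only for preformed vitamin A (retinol and retinyl esters) from animal foods; set ND for a plant-sourced profile whose vitamin A derives from carotenoids
vitamin_b6,1.3,RDA,100,mg,
folate,400,RDA,1000,mcg,UL applies only to synthetic folate from supplements and fortified foods; food folate has no known adverse level
vitamin_b12,2.4,RDA,ND,mcg,Supplements or fortified foods recommended on plant-based diets
vitamin_c,90,RDA,2000,mg,
vitamin_d,600,RDA,4000,IU,Supplements or fortified foods recommended on plant-based diets
vitamin_e,15,RDA,1000,mg,
calcium,1000,RDA,2500,mg,Bioavailability of plant calcium is reduced by oxalates and phytates; hypercalcemia is chiefly supplement-related
iron,8,RDA,45,mg,Vegetarian reference intake is 80% above the omnivorous value owing to non-heme iron bioavailability
magnesium,400,RDA,350,mg,UL applies to pharmacological sources only; food magnesium is exempt
phosphorus,700,RDA,4000,mg,Phosphate is renally regulated; slight dietary excess unlikely to harm healthy adults
potassium,3400,AI,ND,mg,
sodium,2300,CDRR,ND,mg,CDRR limit; athletes with high sweat sodium losses may have different individual needs
zinc,11,RDA,40,mg,Homeostatic absorption adjustments reported on vegetarian diets
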
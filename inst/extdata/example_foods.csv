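food_code,description,cfg_group,cfg_subgroup,reference_amount_g,cfg_serving_g,fat_g_ra,satfat_g_ra,sugars_g_ra,sodium_mg_ra,energy_kcal_100g,is_alcoholic,is_beverage
F001,"apple, raw",VEG_FRUIT,fruit,140,140,0.2,0.05,5.9,1,52,FALSE,FALSE
F002,"french fried potatoes",VEG_FRUIT,potatoes,85,85,14,2.3,0.5,400,310,FALSE,FALSE
F003,"whole wheat bread",GRAIN,whole_grain_breads,35,35,1.8,0.4,2.5,180,250,FALSE,FALSE
F004,"cheddar cheese",MILK_ALT,cheese,30,50,10,6,0.2,190,400,FALSE,FALSE
F005,"peanuts, salted",MEAT_ALT,nuts_seeds,50,60,25,3.5,2,230,600,FALSE,FALSE
F006,"almonds, unsalted",MEAT_ALT,nuts_seeds,50,60,25,1.9,2,0,580,FALSE,FALSE
F007,"cola soft drink",UNCLASSIFIED,high_cal_beverage,355,,0,0,39,15,42,FALSE,TRUE
F008,"diet cola",UNCLASSIFIED,low_cal_beverage,355,,0,0,0,28,1,FALSE,TRUE
F009,"beer, 5% alcohol",UNCLASSIFIED,alcoholic_beverage,341,,0,0,0,14,43,TRUE,TRUE
F010,"olive oil",UNCLASSIFIED,unsat_fats_oils,14,,14,1.9,0,0,884,FALSE,FALSE
F011,"milk, 2% fat",MILK_ALT,milk_fortified_beverages,258,258,5,3,12,120,50,FALSE,TRUE
F012,"milk chocolate bar",UNCLASSIFIED,high_fat_sugar_foods,42,,13,8,24,30,535,FALSE,FALSE
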
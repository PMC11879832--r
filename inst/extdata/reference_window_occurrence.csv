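code,tp,tn,fp,fn,acc
Last_months_mood,38,0,0,0,1.00
Sui_method_circum.,38,0,0,0,1.00
Last_months_behaviour,37,0,0,1,0.97
Last_months_contact,37,0,0,1,0.97
Last_contact,36,0,2,0,0.95
Method_motivation,36,0,2,0,0.95
Location_characteristics,33,0,0,5,0.87
Last_months_relation,31,1,5,1,0.84
Last_months_ideation,32,0,3,3,0.84
Location_proximity,32,0,6,0,0.84
Last_months_behav. change,30,0,7,1,0.79
Location_open tracks,21,8,3,6,0.76
Travel to site_bicycle,8,21,6,3,0.76
Last_months_healthcare,25,3,4,6,0.74
Travel to site_car,9,18,11,0,0.71
Sui_prep_information,24,3,6,5,0.71
Sui prep_practical matters,8,19,3,8,0.71
Sui comm_farewellnote,21,6,3,8,0.71
Travel to site_walk,12,14,8,4,0.68
Sui prep_left significant object,5,19,14,0,0.63
Last_months_appearance,8,14,3,13,0.58
Sui prep_scouting at location,17,5,8,8,0.58
Location_familiarity,20,1,16,1,0.55
Sui prep_substance use,20,1,3,14,0.55
Sui prep_alone at time of death,12,9,6,11,0.55
Hist_sui comm,16,4,2,16,0.53
Sui prep_planning,7,10,16,5,0.45
Last_months_ALE,17,0,1,20,0.45
Location_station,7,8,23,0,0.39
Sui comm_written,10,5,19,4,0.39
Sui comm_SoMe,9,4,18,7,0.34
Travel to site_pubtrans,5,3,30,0,0.21
Travel to site_other,3,0,35,0,0.08
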
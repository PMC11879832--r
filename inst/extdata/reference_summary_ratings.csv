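code,rater,good,adequate,poor
Sui comm_farewellnote,1,34,2,2
Last_months_contact,1,31,4,3
Last_months_mood,1,31,6,1
Location_familiarity,1,31,4,3
Location_open tracks,1,31,2,5
Sui prep_alone at time of death,1,30,3,5
Last_months_appearance,1,29,2,7
Travel to site_bicycle,1,29,2,7
Location_characteristics,1,29,5,4
Sui_method_circum.,1,28,9,1
Sui prep_practical matters,1,28,1,9
Last_months_relation,1,27,8,3
Travel to site_car,1,27,1,10
Last_months_behaviour,1,26,8,4
Last_months_healthcare,1,26,5,7
Travel to site_walk,1,26,1,11
Sui prep_left significant object,1,26,11,1
Last_contact,1,25,12,1
Last_months_SI,1,25,9,4
Location_proximity,1,25,10,3
Last_months_behav. change,1,24,9,5
Sui prep_planning,1,24,7,7
Sui comm_SoMe,1,24,11,3
Sui prep_scouting at location,1,20,8,10
Sui prep_substance use,1,19,14,5
Location_station,1,18,10,10
Sui prep_information,1,18,11,9
Sui comm_written,1,16,19,3
Method_motivation,1,15,19,4
Travel to site_other,1,8,19,11
Travel to site_Pubtrans,1,8,10,20
Hist_sui comm,1,6,4,28
Last_months_ALEs,1,0,3,35
Sui comm_farewellnote,2,22,7,9
Last_months_contact,2,20,17,1
Last_months_mood,2,22,13,3
Location_familiarity,2,28,7,3
Location_open tracks,2,32,0,6
Sui prep_alone at time of death,2,23,3,12
Last_months_appearance,2,26,4,8
Travel to site_bicycle,2,31,0,7
Location_characteristics,2,27,6,5
Sui_method_circum.,2,24,12,2
Sui prep_practical matters,2,15,12,11
Last_months_relation,2,18,16,4
Travel to site_car,2,27,3,8
Last_months_behaviour,2,24,11,3
Last_months_healthcare,2,22,6,10
Travel to site_walk,2,22,7,9
Sui prep_left significant object,2,29,5,4
Last_contact,2,20,14,4
Last_months_SI,2,22,14,2
Location_proximity,2,30,7,1
Last_months_behav. change,2,20,14,4
Sui prep_planning,2,31,4,3
Sui comm_SoMe,2,26,9,3
Sui prep_scouting at location,2,24,2,12
Sui prep_substance use,2,25,8,5
Location_station,2,19,12,7
Sui prep_information,2,21,9,8
Sui comm_written,2,21,13,4
Method_motivation,2,11,22,5
Travel to site_other,2,4,23,11
Travel to site_Pubtrans,2,8,12,18
Hist_sui comm,2,3,1,34
Last_months_ALEs,2,2,2,34
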
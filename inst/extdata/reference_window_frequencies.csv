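code,llm_count,researcher_count,factor
Travel to site__other,77,6,12.8
Travel to site__pubtrans,56,7,8.0
Location_station,47,14,3.4
Travel to site__car,29,13,2.2
Location_familiarity,72,34,2.1
Sui comm_social media,45,24,1.9
Sui comm_written,61,35,1.7
Location_proximity,82,50,1.6
Sui prep_left significant object,29,18,1.6
Method_motivation,97,71,1.4
Sui prep_planning,48,39,1.2
Travel to site_bicycle,23,19,1.2
Travel to site_walking,24,25,1.0
Last_contact,115,122,0.9
Sui prep_gather information,47,58,0.8
Sui prep_substance use,40,50,0.8
Last_months_behav. change,128,164,0.8
Location_open tracks,29,39,0.7
Last_months_SI,124,171,0.7
Sui prep_alone at time of death,26,36,0.7
Sui_method_circum.,70,102,0.7
Sui prep_scouting at location,34,51,0.7
Last_months_behaviour,240,390,0.6
Last_months_relation,127,225,0.6
Last_months_healthcare,116,235,0.5
Sui prep_practicalmatters,25,53,0.5
Last_months_appearance,19,42,0.5
Location_characteristics,44,111,0.4
Sui comm_farewellnote,42,107,0.4
Last_months_mood,139,355,0.4
Last_months_contact,127,444,0.3
Last_months_ALE,26,167,0.2
Hist_sui comm,26,193,0.1
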
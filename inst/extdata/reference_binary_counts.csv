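code,count,tp,tn,fp,fn,sens,spec,acc,ck
Travel to site_car,24,12,12,0,0,1.00,1.00,1.00,1.00
Sui prep_left significant object,34,17,16,1,0,0.94,1.00,0.97,0.94
Sui prep_substance use,98,47,47,2,2,0.96,0.96,0.96,0.92
Travel to site_bicycle,36,17,17,1,1,0.94,0.94,0.94,0.89
Sui prep_gather information,114,54,53,4,3,0.93,0.95,0.94,0.88
Travel to site_pub. trans.,12,6,5,1,0,0.86,1.00,0.92,0.83
Sui_comm_farewell note,212,106,88,18,0,0.85,1.00,0.92,0.83
Sui_comm_social media,46,23,19,4,0,0.85,1.00,0.91,0.83
Travel to site_other,10,5,4,1,0,0.83,1.00,0.90,0.80
Sui_comm_written,68,33,28,6,1,0.85,0.97,0.90,0.79
Location_characteristics,220,109,88,22,1,0.83,0.99,0.90,0.79
Sui prep_alone at time of death,70,30,32,3,5,0.91,0.86,0.89,0.77
Sui prep_scouting at location,100,41,47,3,9,0.93,0.84,0.88,0.76
Travel to site_walk,48,22,20,4,2,0.85,0.91,0.88,0.75
Location_open tracks,76,32,34,4,6,0.89,0.85,0.87,0.74
Location_proximity,98,49,35,14,0,0.78,1.00,0.86,0.71
Sui prep _practical matters,104,40,47,5,12,0.89,0.80,0.84,0.67
Last_contact,242,121,81,40,0,0.75,1.00,0.84,0.67
Location_familiarity,66,33,22,11,0,0.75,1.00,0.83,0.67
Last_months_appearance,82,27,41,0,14,1.00,0.75,0.83,0.66
Method_motivation,140,67,49,21,3,0.76,0.94,0.83,0.66
Last_months_healthcare,468,224,163,71,10,0.76,0.94,0.83,0.65
Sui prep_planning,76,27,35,3,11,0.90,0.76,0.82,0.63
Location_station,26,13,8,5,0,0.72,1.00,0.81,0.62
Sui_method_circum.,202,93,68,33,8,0.74,0.89,0.80,0.59
Last_months_contact,886,407,278,165,36,0.71,0.89,0.77,0.55
Last_months_ideation,340,157,104,66,13,0.70,0.89,0.77,0.54
Last_months_relation,448,182,160,64,42,0.74,0.79,0.76,0.53
Last_months_behav. change,326,155,89,74,8,0.68,0.92,0.75,0.50
Last_months_mood,708,341,183,171,13,0.67,0.93,0.74,0.48
Last_months_ALE,332,97,142,24,69,0.80,0.67,0.72,0.44
Hist_suicide related comm.,384,160,85,107,32,0.60,0.73,0.64,0.28
Last_months_behaviour,778,365,118,271,24,0.57,0.83,0.62,0.24
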
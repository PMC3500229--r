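person_id,encounter_type,sampled,adjudicated,adjudicated_status,adjudicated_subtype
REF-N001,inpatient_secondary,yes,yes,incident_diabetes,unspecified
REF-N002,inpatient_secondary,yes,yes,possible_diabetes,not_applicable
REF-N003,inpatient_secondary,yes,yes,subthreshold_hyperglycemia,not_applicable
REF-N004,inpatient_secondary,yes,yes,miscoded,not_applicable
REF-N005,outpatient,yes,yes,incident_diabetes,unspecified
REF-N006,outpatient,yes,yes,incident_diabetes,unspecified
REF-N007,outpatient,yes,yes,incident_diabetes,unspecified
REF-N008,outpatient,yes,yes,incident_diabetes,unspecified
REF-N009,outpatient,yes,yes,possible_diabetes,not_applicable
REF-N010,outpatient,yes,yes,subthreshold_hyperglycemia,not_applicable
REF-N011,outpatient,yes,yes,subthreshold_hyperglycemia,not_applicable
REF-N012,outpatient,yes,yes,subthreshold_hyperglycemia,not_applicable
REF-N013,outpatient,yes,yes,subthreshold_hyperglycemia,not_applicable
REF-N014,outpatient,yes,yes,lab_rule_out,not_applicable
REF-N015,outpatient,yes,yes,miscoded,not_applicable
REF-N016,prescription,yes,yes,prevalent_diabetes,not_applicable
REF-N017,prescription,yes,yes,possible_diabetes,not_applicable
REF-N018,prescription,yes,yes,possible_diabetes,not_applicable
REF-N019,prescription,yes,yes,possible_diabetes,not_applicable
REF-N020,prescription,yes,yes,possible_diabetes,not_applicable
REF-N021,prescription,yes,yes,possible_diabetes,not_applicable
REF-N022,prescription,yes,yes,subthreshold_hyperglycemia,not_applicable
REF-N023,prescription,yes,yes,subthreshold_hyperglycemia,not_applicable
REF-N024,prescription,yes,yes,pcos,not_applicable
REF-N025,prescription,yes,yes,pcos,not_applicable
REF-N026,prescription,yes,yes,pcos,not_applicable
REF-N027,prescription,yes,yes,pcos,not_applicable
REF-N028,prescription,yes,yes,pcos,not_applicable
REF-N029,prescription,yes,yes,pcos,not_applicable
REF-N030,prescription,yes,yes,lab_rule_out,not_applicable
REF-N031,inpatient_secondary,yes,no,,
REF-N032,inpatient_secondary,yes,no,,
REF-N033,inpatient_secondary,yes,no,,
REF-N034,inpatient_secondary,yes,no,,
REF-N035,inpatient_secondary,yes,no,,
REF-N036,outpatient,yes,no,,
REF-N037,outpatient,yes,no,,
REF-N038,outpatient,yes,no,,
REF-N039,outpatient,yes,no,,
REF-N040,outpatient,yes,no,,
REF-N041,outpatient,yes,no,,
REF-N042,outpatient,yes,no,,
REF-N043,outpatient,yes,no,,
REF-N044,outpatient,yes,no,,
REF-N045,outpatient,yes,no,,
REF-N046,outpatient,yes,no,,
REF-N047,outpatient,yes,no,,
REF-N048,outpatient,yes,no,,
REF-N049,outpatient,yes,no,,
REF-N050,outpatient,yes,no,,
REF-N051,outpatient,yes,no,,
REF-N052,outpatient,yes,no,,
REF-N053,outpatient,yes,no,,
REF-N054,outpatient,yes,no,,
REF-N055,outpatient,yes,no,,
REF-N056,outpatient,yes,no,,
REF-N057,outpatient,yes,no,,
REF-N058,outpatient,yes,no,,
REF-N059,outpatient,yes,no,,
REF-N060,outpatient,yes,no,,
REF-N061,outpatient,yes,no,,
REF-N062,outpatient,yes,no,,
REF-N063,outpatient,yes,no,,
REF-N064,prescription,yes,no,,
REF-N065,prescription,yes,no,,
REF-N066,prescription,yes,no,,
REF-N067,prescription,yes,no,,
REF-N068,prescription,yes,no,,
REF-N069,prescription,yes,no,,
REF-N070,prescription,yes,no,,
REF-N071,prescription,yes,no,,
REF-N072,prescription,yes,no,,
REF-N073,prescription,yes,no,,
REF-N074,prescription,yes,no,,
REF-N075,prescription,yes,no,,
REF-N076,prescription,yes,no,,
REF-N077,prescription,yes,no,,
REF-N078,prescription,yes,no,,
REF-N079,prescription,yes,no,,
REF-N080,prescription,yes,no,,
REF-N081,prescription,yes,no,,
REF-N082,prescription,yes,no,,
REF-N083,prescription,yes,no,,
REF-N084,prescription,yes,no,,
REF-N085,prescription,yes,no,,
REF-N086,prescription,yes,no,,
REF-N087,prescription,yes,no,,
REF-N088,prescription,yes,no,,
REF-N089,prescription,yes,no,,
REF-N090,prescription,yes,no,,
REF-N091,prescription,yes,no,,
REF-N092,prescription,yes,no,,
REF-N093,prescription,yes,no,,
REF-N094,prescription,yes,no,,
REF-N095,prescription,yes,no,,
REF-N096,prescription,yes,no,,
REF-N097,prescription,yes,no,,
REF-N098,prescription,yes,no,,
REF-N099,prescription,yes,no,,
REF-N100,prescription,yes,no,,
REF-N101,prescription,yes,no,,
REF-N102,prescription,yes,no,,
REF-N103,prescription,yes,no,,
REF-N104,prescription,yes,no,,
REF-N105,prescription,yes,no,,
REF-N106,prescription,yes,no,,
REF-N107,prescription,yes,no,,
REF-N108,prescription,yes,no,,
REF-N109,prescription,yes,no,,
REF-N110,prescription,yes,no,,
REF-N111,prescription,yes,no,,
REF-N112,prescription,yes,no,,
REF-N113,prescription,yes,no,,
REF-N114,inpatient_secondary,no,no,,
REF-N115,inpatient_secondary,no,no,,
REF-N116,inpatient_secondary,no,no,,
REF-N117,inpatient_secondary,no,no,,
REF-N118,inpatient_secondary,no,no,,
REF-N119,inpatient_secondary,no,no,,
REF-N120,outpatient,no,no,,
REF-N121,outpatient,no,no,,
REF-N122,outpatient,no,no,,
REF-N123,outpatient,no,no,,
REF-N124,outpatient,no,no,,
REF-N125,outpatient,no,no,,
REF-N126,outpatient,no,no,,
REF-N127,outpatient,no,no,,
REF-N128,outpatient,no,no,,
REF-N129,outpatient,no,no,,
REF-N130,outpatient,no,no,,
REF-N131,outpatient,no,no,,
REF-N132,outpatient,no,no,,
REF-N133,outpatient,no,no,,
REF-N134,outpatient,no,no,,
REF-N135,outpatient,no,no,,
REF-N136,outpatient,no,no,,
REF-N137,outpatient,no,no,,
REF-N138,outpatient,no,no,,
REF-N139,outpatient,no,no,,
REF-N140,outpatient,no,no,,
REF-N141,outpatient,no,no,,
REF-N142,outpatient,no,no,,
REF-N143,outpatient,no,no,,
REF-N144,outpatient,no,no,,
REF-N145,outpatient,no,no,,
REF-N146,prescription,no,no,,
REF-N147,prescription,no,no,,
REF-N148,prescription,no,no,,
REF-N149,prescription,no,no,,
REF-N150,prescription,no,no,,
REF-N151,prescription,no,no,,
REF-N152,prescription,no,no,,
REF-N153,prescription,no,no,,
REF-N154,prescription,no,no,,
REF-N155,prescription,no,no,,
REF-N156,prescription,no,no,,
REF-N157,prescription,no,no,,
REF-N158,prescription,no,no,,
REF-N159,prescription,no,no,,
REF-N160,prescription,no,no,,
REF-N161,prescription,no,no,,
REF-N162,prescription,no,no,,
REF-N163,prescription,no,no,,
REF-N164,prescription,no,no,,
REF-N165,prescription,no,no,,
REF-N166,prescription,no,no,,
REF-N167,prescription,no,no,,
REF-N168,prescription,no,no,,
REF-N169,prescription,no,no,,
REF-N170,prescription,no,no,,
REF-N171,prescription,no,no,,
REF-N172,prescription,no,no,,
REF-N173,prescription,no,no,,
REF-N174,prescription,no,no,,
REF-N175,prescription,no,no,,
REF-N176,prescription,no,no,,
REF-N177,prescription,no,no,,
REF-N178,prescription,no,no,,
REF-N179,prescription,no,no,,
REF-N180,prescription,no,no,,
REF-N181,prescription,no,no,,
REF-N182,prescription,no,no,,
REF-N183,prescription,no,no,,
REF-N184,prescription,no,no,,
REF-N185,prescription,no,no,,
REF-N186,prescription,no,no,,
REF-N187,prescription,no,no,,
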
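person_id,computer_subtype,adjudicated,adjudicated_status,adjudicated_subtype
REF-M001,type1,yes,incident_diabetes,type1
REF-M002,type1,yes,incident_diabetes,type1
REF-M003,type1,yes,incident_diabetes,type1
REF-M004,type1,yes,incident_diabetes,type1
REF-M005,type1,yes,incident_diabetes,type1
REF-M006,type1,yes,incident_diabetes,type1
REF-M007,type1,yes,incident_diabetes,type1
REF-M008,type1,yes,incident_diabetes,type1
REF-M009,type1,yes,incident_diabetes,type1
REF-M010,type1,yes,incident_diabetes,type1
REF-M011,type1,yes,incident_diabetes,type1
REF-M012,type1,yes,incident_diabetes,type1
REF-M013,type1,yes,incident_diabetes,type2
REF-M014,type1,yes,incident_diabetes,type2
REF-M015,type1,yes,prevalent_diabetes,not_applicable
REF-M016,type2,yes,incident_diabetes,type1
REF-M017,type2,yes,incident_diabetes,type2
REF-M018,type2,yes,incident_diabetes,type2
REF-M019,type2,yes,incident_diabetes,type2
REF-M020,type2,yes,incident_diabetes,type2
REF-M021,type2,yes,incident_diabetes,type2
REF-M022,type2,yes,incident_diabetes,type2
REF-M023,type2,yes,incident_diabetes,type2
REF-M024,type2,yes,incident_diabetes,type2
REF-M025,type2,yes,incident_diabetes,type2
REF-M026,type2,yes,incident_diabetes,type2
REF-M027,type2,yes,incident_diabetes,type2
REF-M028,type2,yes,incident_diabetes,type2
REF-M029,type2,yes,incident_diabetes,type2
REF-M030,type2,yes,incident_diabetes,type2
REF-M031,type2,yes,incident_diabetes,type2
REF-M032,type2,yes,incident_diabetes,type2
REF-M033,type2,yes,incident_diabetes,type2
REF-M034,type2,yes,incident_diabetes,type2
REF-M035,type2,yes,incident_diabetes,type2
REF-M036,type2,yes,incident_diabetes,type2
REF-M037,type2,yes,incident_diabetes,type2
REF-M038,type2,yes,incident_diabetes,type2
REF-M039,type2,yes,incident_diabetes,type2
REF-M040,type2,yes,incident_diabetes,unspecified
REF-M041,type2,yes,incident_diabetes,unspecified
REF-M042,type2,yes,incident_diabetes,unspecified
REF-M043,type2,yes,subthreshold_hyperglycemia,not_applicable
REF-M044,type2,yes,subthreshold_hyperglycemia,not_applicable
REF-M045,type2,yes,subthreshold_hyperglycemia,not_applicable
REF-M046,type2,yes,pcos,not_applicable
REF-M047,type1,no,,
REF-M048,type1,no,,
REF-M049,type1,no,,
REF-M050,type1,no,,
REF-M051,type1,no,,
REF-M052,type1,no,,
REF-M053,type2,no,,
REF-M054,type2,no,,
REF-M055,type2,no,,
REF-M056,type2,no,,
REF-M057,type2,no,,
REF-M058,type2,no,,
REF-M059,type2,no,,
REF-M060,type2,no,,
REF-M061,type2,no,,
REF-M062,type2,no,,
REF-M063,type2,no,,
REF-M064,type2,no,,
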
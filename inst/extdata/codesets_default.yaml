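# Default clinical code sets for the incident-diabetes case definition.
# Diagnosis and procedure codes may be written dotted or decimal-free; they
# are normalized on load. Any set may be overridden by a user config.
name: default
# Restricted diabetes list accepted as a PRIMARY inpatient discharge
# diagnosis: family 250 unspecified plus fourth-digit subcategories .0-.3
# (uncomplicated through ketoacidosis/coma) and .9; chronic-complication
# subcategories .4-.8 are deliberately absent (they indicate established,
# not newly diagnosed, diabetes).
dx_diabetes_primary_inpatient:
  - "250"
  - "250.0"
  - "250.1"
  - "250.2"
  - "250.3"
  - "250.9"
# Any diagnosis of diabetes mellitus (whole 250 family) for secondary /
# admission / outpatient positions and confirmation searches.
dx_diabetes_general:
  - "250"
# Polycystic ovarian syndrome (polycystic ovaries).
dx_pcos:
  - "256.4"
# Absence / irregularity of menstruation (PCOS-adjacent indications for
# oral hypoglycemics).
dx_menses_abnormal:
  - "626.0"
  - "626.1"
  - "626.4"
# Drug classification comes from an explicit drug_class column in the
# prescription table; these sets list the class labels counting toward each
# role.
drug_insulin:
  - insulin
drug_insulin_adjunct:
  - insulin_adjunct
drug_oral_hypoglycemic:
  - oral_hypoglycemic
# Procedures indicating diabetes management: glycosylated hemoglobin plus
# quantitative glucose and glucose-tolerance testing (CPT-style codes;
# configurable, sites differ).
proc_diabetes_management:
  - "83036"
  - "82947"
  - "82950"
  - "82951"
# Glycosylated hemoglobin (HbA1c) alone -- the secondary definition's
# outpatient confirmation.
proc_glycosylated_hemoglobin:
  - "83036"
# Diabetes-related procedures eligible to reset the index date to an earlier
# testing visit; defaults to the management set.
proc_diabetes_related:
  - "83036"
  - "82947"
  - "82950"
  - "82951"
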
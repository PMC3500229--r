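# Builders for small hand-made claims datasets. The default test person is
# enrolled continuously 1999-2007, initiates a psychotropic in mid-2001 at
# about age 11, and has one baseline visit, so baseline eligibility holds
# unless a test breaks it on purpose.

d <- function(s) as.Date(s)

TZ <- d("2001-06-01")         # default qualifying fill / time zero
FU_START <- TZ + 1
FU_END <- TZ + 395            # drug-discontinuation bound (30 + 365)

ov_row <- function(date, primary, secondary = "", setting = "outpatient",
                   person_id = "A") {
  data.frame(person_id = person_id, visit_date = d(date), primary_dx = primary,
             secondary_dx = secondary, setting = setting,
             stringsAsFactors = FALSE)
}

ip_row <- function(adm, disc, primary = "", secondary = "", admission = "",
                   person_id = "A") {
  data.frame(person_id = person_id, admission_date = d(adm),
             discharge_date = d(disc), primary_dx = primary,
             secondary_dx = secondary, admission_dx = admission,
             stringsAsFactors = FALSE)
}

rx_row <- function(date, class, name = "drug", person_id = "A") {
  data.frame(person_id = person_id, fill_date = d(date), drug_class = class,
             drug_name = name, stringsAsFactors = FALSE)
}

pc_row <- function(date, code, person_id = "A") {
  data.frame(person_id = person_id, service_date = d(date),
             procedure_code = code, stringsAsFactors = FALSE)
}

flag_row <- function(flag, start, end, person_id = "A") {
  data.frame(person_id = person_id, flag = flag, start_date = d(start),
             end_date = d(end), stringsAsFactors = FALSE)
}

# One-person dataset with sane defaults; extra claims appended to the
# baseline scaffolding (psychotropic fill at TZ, routine visit 6 months
# before).
one_person <- function(outpatient = NULL, inpatient = NULL,
                       prescriptions = NULL, procedures = NULL,
                       exclusion_flags = NULL, birth = "1990-07-15",
                       enroll_start = "1999-01-01", enroll_end = "2007-12-31",
                       baseline = TRUE, person_id = "A") {
  persons <- data.frame(person_id = person_id, birth_date = d(birth),
                        sex = "F", stringsAsFactors = FALSE)
  enrollment <- data.frame(person_id = person_id, start_date = d(enroll_start),
                           end_date = d(enroll_end), stringsAsFactors = FALSE)
  base_ov <- if (baseline) ov_row("2000-12-01", "V700", person_id = person_id)
  base_rx <- if (baseline) rx_row("2001-06-01", "study_psychotropic",
                                  "risperidone", person_id = person_id)
  claims_dataset(persons = persons, enrollment = enrollment,
                 inpatient = inpatient,
                 outpatient = rbind(base_ov, outpatient),
                 prescriptions = rbind(base_rx, prescriptions),
                 procedures = procedures, exclusion_flags = exclusion_flags)
}

member_a <- function(fstart = FU_START, fend = FU_END, person_id = "A") {
  list(person_id = person_id, followup_start = fstart, followup_end = fend)
}

# Shorthand: verdict of the default member for a one-person dataset.
verdict <- function(ds, variant = "primary", fstart = FU_START, fend = FU_END,
                    config = phenotype_config(), person_id = "A") {
  apply_definition(ds, member_a(fstart, fend, person_id),
                   variant = variant, config = config)
}
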
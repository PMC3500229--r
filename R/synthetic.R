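# Seeded synthetic claims generator with planted ground truth. Each person is
# assigned one scenario from the misclassification taxonomy observed in
# claims-based diabetes ascertainment: canonical incident type 1 / type 2
# care sequences, diabetes managed by lifestyle alone, prevalent diabetes,
# PCOS treated with metformin, single rule-out diagnoses, subthreshold
# hyperglycemia, miscoded inpatient diagnoses, and healthy controls. The
# generator emits the standard claims tables plus the cohort window, a truth
# record, and adjudication labels derived from truth, so the engine and the
# validation statistics are testable end to end without real data.

SCENARIOS <- c("canonical_t1d", "canonical_t2d_rx", "t2d_lifestyle_only",
               "prevalent_diabetes", "pcos_metformin", "rule_out_single_dx",
               "subthreshold_hyperglycemia_dx", "miscoded_dx", "healthy")

#' Scenario configuration for the synthetic claims generator
#'
#' @param n_persons Number of persons to generate.
#' @param scenario_mix Named numeric vector of scenario probabilities over
#'   `canonical_t1d`, `canonical_t2d_rx`, `t2d_lifestyle_only`,
#'   `prevalent_diabetes`, `pcos_metformin`, `rule_out_single_dx`,
#'   `subthreshold_hyperglycemia_dx`, `miscoded_dx`, `healthy`; must sum
#'   to 1. Scenarios may be omitted (probability 0).
#' @param seed Integer seed; all randomness flows from it through fixed-width
#'   per-person draw rows, so the same config and seed give byte-identical
#'   output.
#' @param study_start,study_end Study window.
#' @param sex_female_prob Probability a person is female (default 0.77,
#'   echoing the predominance of young women in psychotropic-initiator
#'   cohorts).
#' @param gap_jitter_mean Mean of the geometric jitter (days) added to
#'   visit gaps; 0 disables jitter.
#' @param p_drop_confirm Probability that a canonical scenario's confirming
#'   claims are dropped (turning it into a missed case); default 0.
#' @param leak_prevalent If `TRUE`, prevalent-diabetes persons' historical
#'   claims are withheld from the dataset (emulating records predating the
#'   data window), so they slip through baseline screening and appear as
#'   false positives; if `FALSE` (default) their prior care is visible and
#'   they are excluded at cohort stage.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_persons = 100L,
                            scenario_mix = c(canonical_t1d = 0.15,
                                             canonical_t2d_rx = 0.25,
                                             t2d_lifestyle_only = 0.10,
                                             prevalent_diabetes = 0.05,
                                             pcos_metformin = 0.10,
                                             rule_out_single_dx = 0.12,
                                             subthreshold_hyperglycemia_dx = 0.08,
                                             miscoded_dx = 0.05,
                                             healthy = 0.10),
                            seed = 1L,
                            study_start = as.Date("1996-01-01"),
                            study_end = as.Date("2007-12-31"),
                            sex_female_prob = 0.77,
                            gap_jitter_mean = 14,
                            p_drop_confirm = 0,
                            leak_prevalent = FALSE) {
  unknown <- setdiff(names(scenario_mix), SCENARIOS)
  if (length(unknown) > 0L) {
    stop("unknown scenario(s) in mix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(scenario_mix) - 1) > 1e-9) {
    stop("scenario_mix probabilities must sum to 1 (got ",
         format(sum(scenario_mix)), ")", call. = FALSE)
  }
  stopifnot(n_persons >= 0, all(scenario_mix >= 0))
  mix <- stats::setNames(rep(0, length(SCENARIOS)), SCENARIOS)
  mix[names(scenario_mix)] <- scenario_mix
  structure(list(n_persons = as.integer(n_persons), scenario_mix = mix,
                 seed = as.integer(seed),
                 study_start = as_date(study_start),
                 study_end = as_date(study_end),
                 sex_female_prob = sex_female_prob,
                 gap_jitter_mean = gap_jitter_mean,
                 p_drop_confirm = p_drop_confirm,
                 leak_prevalent = isTRUE(leak_prevalent)),
            class = "scenario_config")
}

#' Generate a synthetic claims dataset with planted truth
#'
#' Every person receives an enrollment history satisfying baseline
#' eligibility, one qualifying psychotropic initiation (time zero), a
#' baseline-utilization visit, and scenario-specific claims during follow-up.
#' Prevalent-diabetes persons additionally carry visible pre-baseline
#' diabetes care unless `leak_prevalent` withholds it.
#'
#' @param config A [scenario_config()].
#' @return List with elements `dataset` (a `claims_dataset`), `cohort` (the
#'   cohort window table for persons passing baseline screening), `truth`
#'   (per-person `TruthRecord` data frame: `person_id`, `scenario`,
#'   `true_incident_diabetes`, `true_onset_date`, `true_subtype`, `subflag`)
#'   and `labels` (adjudication labels derived from truth).
#' @export
generate_claims <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_persons
  if (n == 0L) {
    ds <- claims_dataset()
    truth <- data.frame(person_id = character(0), scenario = character(0),
                        true_incident_diabetes = logical(0),
                        true_onset_date = as.Date(character(0)),
                        true_subtype = character(0), subflag = character(0),
                        stringsAsFactors = FALSE)
    return(list(dataset = ds,
                cohort = build_cohort(ds),
                truth = truth,
                labels = derive_adjudication_labels(truth)))
  }

  set.seed(config$seed)
  n_draws <- 12L
  U <- matrix(stats::runif(n * n_draws), nrow = n, ncol = n_draws)

  jit <- function(u, cap) {
    if (config$gap_jitter_mean <= 0) return(rep(0L, length(u)))
    pmin(as.integer(stats::qgeom(u, 1 / (config$gap_jitter_mean + 1))), cap)
  }

  ids <- sprintf("P%05d", seq_len(n))
  cum <- cumsum(config$scenario_mix)
  scenario <- SCENARIOS[findInterval(U[, 1], cum) + 1L]
  scenario[U[, 1] >= 1] <- SCENARIOS[length(SCENARIOS)]
  sex <- ifelse(U[, 2] < config$sex_female_prob, "F", "M")

  span <- as.integer(config$study_end - config$study_start)
  tz <- config$study_start + 370L + floor(U[, 4] * (span - 370L - 600L))
  age_years <- 6.05 + U[, 3] * 17.9
  birth <- tz - round(age_years * 365.25)
  enrol_start <- tz - 380L - floor(U[, 5] * 100)
  baseline_visit <- tz - 100L - floor(U[, 6] * 200)
  d0 <- tz + 21L + jit(U[, 7], 120L)
  j2 <- jit(U[, 8], 30L)
  t1d_inpatient <- U[, 9] < 0.4
  ruleout_lab <- U[, 10] < 0.3
  dropped <- U[, 11] < config$p_drop_confirm

  ov <- list(); ip <- list(); rx <- list(); pr <- list()
  add_ov <- function(sel, date, primary, secondary = "", setting = "outpatient") {
    if (any(sel)) {
      ov[[length(ov) + 1L]] <<- data.frame(
        person_id = ids[sel], visit_date = date[sel], primary_dx = primary,
        secondary_dx = secondary, setting = setting, stringsAsFactors = FALSE)
    }
  }
  add_ip <- function(sel, adm, disc, primary, secondary = "") {
    if (any(sel)) {
      ip[[length(ip) + 1L]] <<- data.frame(
        person_id = ids[sel], admission_date = adm[sel],
        discharge_date = disc[sel], primary_dx = primary,
        secondary_dx = secondary, admission_dx = "", stringsAsFactors = FALSE)
    }
  }
  add_rx <- function(sel, date, class, name) {
    if (any(sel)) {
      rx[[length(rx) + 1L]] <<- data.frame(
        person_id = ids[sel], fill_date = date[sel], drug_class = class,
        drug_name = name, stringsAsFactors = FALSE)
    }
  }
  add_pr <- function(sel, date, code) {
    if (any(sel)) {
      pr[[length(pr) + 1L]] <<- data.frame(
        person_id = ids[sel], service_date = date[sel], procedure_code = code,
        stringsAsFactors = FALSE)
    }
  }

  all_p <- rep(TRUE, n)
  add_ov(all_p, baseline_visit, "V700")
  add_rx(all_p, tz, "study_psychotropic", "risperidone")

  s <- scenario == "canonical_t1d" & t1d_inpatient
  add_ip(s, d0, d0 + 3L, "25011")
  add_rx(s, d0 + 4L, "insulin", "insulin glargine")
  add_rx(s, d0 + 34L, "insulin", "insulin glargine")

  s <- scenario == "canonical_t1d" & !t1d_inpatient
  add_ov(s, d0, "25001")
  sk <- s & !dropped
  add_rx(sk, d0 + 3L + j2, "insulin", "insulin lispro")
  add_rx(sk, d0 + 45L, "insulin", "insulin lispro")

  s <- scenario == "canonical_t2d_rx"
  add_ov(s, d0, "25000")
  sk <- s & !dropped
  add_rx(sk, d0 + 7L + j2, "oral_hypoglycemic", "metformin")
  add_pr(sk, d0 + 7L + j2, "83036")
  add_rx(sk, d0 + 45L, "oral_hypoglycemic", "metformin")

  s <- scenario == "t2d_lifestyle_only"
  add_ov(s, d0, "25000")
  add_pr(s & !dropped, d0 + 10L + j2, "83036")

  s <- scenario == "prevalent_diabetes"
  if (!config$leak_prevalent) {
    add_ov(s, tz - 200L, "25000")
    add_rx(s, tz - 190L, "insulin", "insulin NPH")
  }
  add_ov(s, d0, "25000")
  add_rx(s, d0 + 5L, "insulin", "insulin NPH")
  add_rx(s, d0 + 35L, "insulin", "insulin NPH")

  s <- scenario == "pcos_metformin"
  add_rx(s, d0, "oral_hypoglycemic", "metformin")
  add_rx(s, d0 + 30L, "oral_hypoglycemic", "metformin")
  add_ov(s, d0 + 10L + j2, "6264", "2564")

  s <- scenario == "rule_out_single_dx"
  add_ov(s, d0, "25000")
  add_pr(s & ruleout_lab, d0, "82947")

  s <- scenario == "subthreshold_hyperglycemia_dx"
  add_ov(s, d0, "25000")
  add_pr(s, d0 + 5L + j2, "82947")

  s <- scenario == "miscoded_dx"
  add_ip(s, d0, d0 + 2L, "29680", "25000")

  s <- scenario == "healthy"
  add_ov(s, d0, "V700")

  persons <- data.frame(person_id = ids, birth_date = birth, sex = sex,
                        stringsAsFactors = FALSE)
  enrollment <- data.frame(person_id = ids, start_date = enrol_start,
                           end_date = config$study_end, stringsAsFactors = FALSE)
  bind <- function(lst, schema) {
    if (length(lst) == 0L) return(NULL)
    do.call(rbind, lst)
  }
  ds <- claims_dataset(persons = persons, enrollment = enrollment,
                       inpatient = bind(ip), outpatient = bind(ov),
                       prescriptions = bind(rx), procedures = bind(pr))

  # cohort windows: all persons pass baseline screening by construction,
  # except prevalent-diabetes persons whose prior care is visible
  in_cohort <- !(scenario == "prevalent_diabetes" & !config$leak_prevalent)
  fu_end <- pmin(config$study_end, nth_birthday(birth, 25L) - 1L, tz + 395L)
  censor <- ifelse(fu_end == config$study_end, "study_end",
                   ifelse(fu_end == nth_birthday(birth, 25L) - 1L, "age_25",
                          "drug_discontinuation_365"))
  cohort <- data.frame(person_id = ids, time_zero = tz,
                       qualifying_fill_date = tz, followup_start = tz + 1L,
                       followup_end = fu_end, censor_reason = censor,
                       stringsAsFactors = FALSE)[in_cohort, , drop = FALSE]
  rownames(cohort) <- NULL

  incident <- scenario %in% c("canonical_t1d", "canonical_t2d_rx",
                              "t2d_lifestyle_only")
  truth <- data.frame(
    person_id = ids, scenario = scenario,
    true_incident_diabetes = incident,
    true_onset_date = as.Date(ifelse(incident, d0, NA), origin = "1970-01-01"),
    true_subtype = ifelse(scenario == "canonical_t1d", "type1",
                          ifelse(incident, "type2", "none")),
    subflag = ifelse(scenario == "rule_out_single_dx",
                     ifelse(ruleout_lab, "lab_rule_out", "possible_diabetes"),
                     ""),
    stringsAsFactors = FALSE)

  list(dataset = ds, cohort = cohort, truth = truth,
       labels = derive_adjudication_labels(truth))
}

#' Derive adjudication labels from generator ground truth
#'
#' Maps each planted scenario onto the adjudication vocabulary a chart-review
#' panel would use: canonical and lifestyle-only streams become
#' `incident_diabetes` with their subtype; PCOS, rule-out, subthreshold,
#' miscoded, prevalent and healthy streams become the corresponding
#' false-positive categories.
#'
#' @param truth Truth data frame from [generate_claims()].
#' @return Data frame with `person_id`, `adjudicated_status`,
#'   `adjudicated_subtype`.
#' @export
derive_adjudication_labels <- function(truth) {
  status <- character(nrow(truth))
  status[truth$scenario %in% c("canonical_t1d", "canonical_t2d_rx",
                               "t2d_lifestyle_only")] <- "incident_diabetes"
  status[truth$scenario == "prevalent_diabetes"] <- "prevalent_diabetes"
  status[truth$scenario == "pcos_metformin"] <- "pcos"
  status[truth$scenario == "subthreshold_hyperglycemia_dx"] <-
    "subthreshold_hyperglycemia"
  status[truth$scenario == "miscoded_dx"] <- "miscoded"
  status[truth$scenario == "healthy"] <- "not_diabetes_other"
  ro <- truth$scenario == "rule_out_single_dx"
  status[ro] <- ifelse(truth$subflag[ro] == "lab_rule_out", "lab_rule_out",
                       "possible_diabetes")
  data.frame(person_id = truth$person_id,
             adjudicated_status = status,
             adjudicated_subtype = ifelse(status == "incident_diabetes",
                                          truth$true_subtype, "not_applicable"),
             stringsAsFactors = FALSE)
}
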
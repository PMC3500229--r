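# The case-definition engine. A member's verdict rests on the FIRST
# diabetes-related medical care encounter of follow-up: a primary inpatient
# discharge diagnosis meets the definition outright; every other encounter
# type must survive the PCOS exclusion window and then be confirmed by a
# later claim of a corroborating kind. Met cases get a final index date
# (possibly reset to an earlier diabetes-related procedure) and a type 1 /
# type 2 subtype.

ENCOUNTER_TYPES <- c("inpatient_primary", "inpatient_secondary", "outpatient",
                     "prescription")

#' Hospital stay period
#'
#' The interval from the day before admission through the day after
#' discharge. Outpatient claims dated inside it are attributed to the
#' hospitalization rather than treated as free-standing encounters.
#'
#' @param admission_date,discharge_date Date vectors (element-wise stays).
#' @return Data frame with `period_start` and `period_end`.
#' @export
#' @examples
#' hospital_stay_period(as.Date("2001-01-10"), as.Date("2001-01-14"))
hospital_stay_period <- function(admission_date, discharge_date) {
  admission_date <- as_date(admission_date)
  discharge_date <- as_date(discharge_date)
  stopifnot(all(admission_date <= discharge_date))
  data.frame(period_start = admission_date - 1, period_end = discharge_date + 1)
}

# dates (numeric or Date) falling inside any of the closed periods
date_in_any_period <- function(dates, period_start, period_end) {
  if (length(dates) == 0L) return(logical(0))
  if (length(period_start) == 0L) return(rep(FALSE, length(dates)))
  d <- as.numeric(dates)
  ps <- as.numeric(period_start)
  pe <- as.numeric(period_end)
  vapply(d, function(x) any(ps <= x & x <= pe), logical(1))
}

# Dates carrying a PCOS diagnosis in any position, inpatient or outpatient.
pcos_dx_dates <- function(pc, registry) {
  dx_match_dates(pc, registry$dx_pcos)
}

#' Is an initial encounter excluded by the PCOS window?
#'
#' True when any polycystic-ovarian-syndrome diagnosis (primary or secondary,
#' inpatient or outpatient) is dated within `[t_x - 120, t_x + 120]` (closed
#' interval; window width configurable).
#'
#' @param dataset A `claims_dataset`.
#' @param person_id Person identifier.
#' @param t_x Initial index date.
#' @param registry A `code_registry`.
#' @param config A [phenotype_config()].
#' @return Logical scalar.
#' @export
pcos_excluded <- function(dataset, person_id, t_x,
                          registry = default_registry(),
                          config = phenotype_config()) {
  pc <- split_claims(dataset)[[person_id]]
  if (is.null(pc)) stop("unknown person_id: ", person_id, call. = FALSE)
  pcos_excluded_for(pc, as_date(t_x), registry, config)
}

pcos_excluded_for <- function(pc, t_x, registry, config) {
  d <- pcos_dx_dates(pc, registry)
  w <- config$pcos_window_days
  any(d >= t_x - w & d <= t_x + w)
}

# Inpatient index-date rule: admission date, or the prior day if an emergency
# or outpatient visit carrying a diabetes diagnosis fell on that day.
inpatient_tx <- function(pc, admission_date, registry) {
  ov <- pc$outpatient
  if (n_claims(ov) > 0L) {
    prior <- ov$visit_date == admission_date - 1 &
      ov$setting %in% c("outpatient", "emergency") &
      (safe_match(registry$dx_diabetes_general, ov$primary_dx) |
         multi_dx_match(registry$dx_diabetes_general, ov$secondary_dx))
    if (any(prior)) return(admission_date - 1)
  }
  admission_date
}

#' Extract diabetes-related medical care encounters within follow-up
#'
#' Emits one candidate encounter per qualifying claim, each with its initial
#' index date `t_x`:
#' * `inpatient_primary` -- stay whose primary discharge diagnosis matches the
#'   restricted inpatient diabetes list; `t_x` is the admission date, or the
#'   prior day if an emergency/outpatient visit with a diabetes diagnosis
#'   fell on that day.
#' * `inpatient_secondary` -- stay with a secondary or admission diabetes
#'   diagnosis, or a professional claim (`setting = "physician_inpatient"`)
#'   with a primary diabetes diagnosis dated within some stay's hospital stay
#'   period; `t_x` follows the inpatient rule for that stay.
#' * `outpatient` -- outpatient or emergency visit with a primary diabetes
#'   diagnosis dated outside every hospital stay period; `t_x` is the visit
#'   date.
#' * `prescription` -- fill of insulin, an insulin adjunct, or an oral
#'   hypoglycemic, provided no PCOS diagnosis falls in
#'   `[t_x - 120, t_x + 120]`; `t_x` is the fill date.
#'
#' An encounter belongs to follow-up when its claim is dated inside the
#' window (the prior-day index rule may place `t_x` one day earlier). Output
#' is ordered by `t_x`, ties broken by encounter strength (inpatient-primary
#' first, prescription last).
#'
#' @param dataset A `claims_dataset`.
#' @param person_id Person identifier.
#' @param followup_start,followup_end Closed follow-up window.
#' @param registry A `code_registry`.
#' @param config A [phenotype_config()].
#' @return Data frame with `person_id`, `encounter_type`, `event_date`
#'   (`t_x`), `claim_date` and `source`.
#' @export
extract_diabetes_encounters <- function(dataset, person_id, followup_start,
                                        followup_end,
                                        registry = default_registry(),
                                        config = phenotype_config()) {
  pc <- split_claims(dataset)[[person_id]]
  if (is.null(pc)) stop("unknown person_id: ", person_id, call. = FALSE)
  enc <- extract_encounters_for(pc, as_date(followup_start),
                                as_date(followup_end), registry, config)
  data.frame(person_id = rep(pc$person$person_id, length(enc$encounter_type)),
             encounter_type = enc$encounter_type,
             event_date = enc$event_date, claim_date = enc$claim_date,
             source = enc$source, stringsAsFactors = FALSE)
}

# Internal workhorse; returns a list of parallel vectors (encounter_type,
# event_date, claim_date, source), ordered.
extract_encounters_for <- function(pc, followup_start, followup_end,
                                   registry, config) {
  types <- character(0)
  event <- claim <- as.Date(character(0))
  src <- character(0)
  add <- function(type, event_date, claim_date, source) {
    n <- length(event_date)
    if (n > 0L) {
      types <<- c(types, rep(type, n))
      event <<- c(event, event_date)
      claim <<- c(claim, claim_date)
      src <<- c(src, source)
    }
  }

  ip <- pc$inpatient
  n_ip <- n_claims(ip)
  if (n_ip > 0L) {
    p_start <- ip$admission_date - 1
    p_end <- ip$discharge_date + 1
    tx_stay <- ip$admission_date
    for (i in seq_len(n_ip)) {
      tx_stay[i] <- inpatient_tx(pc, ip$admission_date[i], registry)
    }

    prim <- safe_match(registry$dx_diabetes_primary_inpatient, ip$primary_dx)
    add("inpatient_primary", tx_stay[prim], ip$admission_date[prim],
        paste0("inpatient:", which(prim)))

    sec <- !prim & (multi_dx_match(registry$dx_diabetes_general, ip$secondary_dx) |
                      multi_dx_match(registry$dx_diabetes_general, ip$admission_dx))
    add("inpatient_secondary", tx_stay[sec], ip$admission_date[sec],
        paste0("inpatient:", which(sec)))

    # professional claims with a primary diabetes diagnosis during a stay
    ov <- pc$outpatient
    phys <- which(ov$setting == "physician_inpatient" &
                    safe_match(registry$dx_diabetes_general, ov$primary_dx))
    for (i in phys) {
      host <- which(p_start <= ov$visit_date[i] & ov$visit_date[i] <= p_end)
      if (length(host) > 0L) {
        host <- host[which.min(ip$admission_date[host])]
        add("inpatient_secondary", tx_stay[host], ip$admission_date[host],
            paste0("outpatient:", i))
      }
    }
  } else {
    p_start <- p_end <- as.Date(character(0))
  }

  ov <- pc$outpatient
  if (n_claims(ov) > 0L) {
    op <- ov$setting %in% c("outpatient", "emergency") &
      safe_match(registry$dx_diabetes_general, ov$primary_dx) &
      !date_in_any_period(ov$visit_date, p_start, p_end)
    add("outpatient", ov$visit_date[op], ov$visit_date[op],
        paste0("outpatient:", which(op)))
  }

  rx <- pc$prescriptions
  if (n_claims(rx) > 0L) {
    dm <- which(rx$drug_class %in% diabetes_drug_classes(registry))
    if (length(dm) > 0L) {
      pcos_d <- as.numeric(pcos_dx_dates(pc, registry))
      w <- config$pcos_window_days
      keep <- if (length(pcos_d) == 0L) {
        rep(TRUE, length(dm))
      } else {
        fd <- as.numeric(rx$fill_date[dm])
        !vapply(fd, function(x) any(pcos_d >= x - w & pcos_d <= x + w),
                logical(1))
      }
      dm <- dm[keep]
      add("prescription", rx$fill_date[dm], rx$fill_date[dm],
          paste0("prescriptions:", dm))
    }
  }

  keep <- claim >= followup_start & claim <= followup_end
  dup <- duplicated(paste(types, event, src))
  keep <- keep & !dup
  ord <- order(event[keep], match(types[keep], ENCOUNTER_TYPES))
  list(encounter_type = types[keep][ord], event_date = event[keep][ord],
       claim_date = claim[keep][ord], source = src[keep][ord])
}

# Confirmation events available to one person: diabetes-medication fills,
# outpatient and inpatient diabetes diagnoses, management and HbA1c
# procedures, abnormal-menses diagnoses.
confirmation_events <- function(pc, registry) {
  ov <- pc$outpatient
  ip <- pc$inpatient
  list(
    dm_fills = sort(pc$prescriptions$fill_date[
      pc$prescriptions$drug_class %in% diabetes_drug_classes(registry)]),
    outpatient_dx = sort(ov$visit_date[
      safe_match(registry$dx_diabetes_general, ov$primary_dx)]),
    inpatient_dx = sort(ip$admission_date[
      safe_match(registry$dx_diabetes_general, ip$primary_dx) |
        multi_dx_match(registry$dx_diabetes_general, ip$secondary_dx) |
        multi_dx_match(registry$dx_diabetes_general, ip$admission_dx)]),
    mgmt_proc = sort(pc$procedures$service_date[
      safe_match(registry$proc_diabetes_management, pc$procedures$procedure_code)]),
    hba1c_proc = sort(pc$procedures$service_date[
      safe_match(registry$proc_glycosylated_hemoglobin, pc$procedures$procedure_code)]),
    menses_dx = dx_match_dates(pc, registry$dx_menses_abnormal)
  )
}

first_in <- function(dates, lo, hi) {
  d <- dates[dates >= lo & dates <= hi]
  if (length(d) == 0L) NULL else d[1]
}

# Confirmation verdict for one initial encounter. Confirming events must be
# strictly after the encounter date and at or before window_end; the
# prescription pathway's management procedure may share a date with the
# second fill.
confirm_encounter_for <- function(pc, encounter_type, enc_date, registry,
                                  variant, window_end, events = NULL) {
  if (encounter_type == "inpatient_primary") {
    return(list(confirmed = TRUE, confirmation = "not_required",
                confirmation_date = as.Date(NA)))
  }
  if (variant == "secondary" && encounter_type == "inpatient_secondary") {
    return(list(confirmed = TRUE, confirmation = "not_required",
                confirmation_date = as.Date(NA)))
  }
  ev <- events %||% confirmation_events(pc, registry)
  lo <- enc_date + 1
  hi <- window_end
  none <- list(confirmed = FALSE, confirmation = "none_found",
               confirmation_date = as.Date(NA))
  if (hi < lo) return(none)

  if (encounter_type == "inpatient_secondary") {
    d <- first_in(ev$dm_fills, lo, hi)
    if (!is.null(d)) return(list(confirmed = TRUE, confirmation = "by_prescription",
                                 confirmation_date = d))
    d <- first_in(c(ev$outpatient_dx, ev$inpatient_dx), lo, hi)
    if (!is.null(d)) return(list(confirmed = TRUE, confirmation = "by_diagnosis",
                                 confirmation_date = d))
    return(none)
  }

  if (encounter_type == "outpatient") {
    d <- first_in(ev$dm_fills, lo, hi)
    if (!is.null(d)) return(list(confirmed = TRUE, confirmation = "by_prescription",
                                 confirmation_date = d))
    d <- first_in(ev$inpatient_dx, lo, hi)
    if (!is.null(d)) return(list(confirmed = TRUE, confirmation = "by_diagnosis",
                                 confirmation_date = d))
    if (variant == "secondary") {
      d <- first_in(ev$hba1c_proc, lo, hi)
      if (!is.null(d)) return(list(confirmed = TRUE,
                                   confirmation = "by_hba1c_procedure",
                                   confirmation_date = d))
    }
    return(none)
  }

  if (encounter_type == "prescription") {
    d <- first_in(c(ev$outpatient_dx, ev$inpatient_dx), lo, hi)
    if (!is.null(d)) return(list(confirmed = TRUE, confirmation = "by_diagnosis",
                                 confirmation_date = d))
    second_fill <- first_in(ev$dm_fills, lo, hi)
    proc <- first_in(ev$mgmt_proc, lo, hi)
    menses <- any(ev$menses_dx >= lo & ev$menses_dx <= hi)
    if (!is.null(second_fill) && !is.null(proc) && !menses) {
      return(list(confirmed = TRUE, confirmation = "by_rx_plus_procedure",
                  confirmation_date = max(second_fill, proc)))
    }
    return(none)
  }
  stop("unknown encounter_type: ", encounter_type, call. = FALSE)
}

#' Confirm an initial diabetes-related encounter
#'
#' Applies the confirmation matrix for the chosen definition variant. A
#' primary inpatient diagnosis needs no confirmation. Under the primary
#' variant: a secondary inpatient diagnosis is confirmed by a later
#' diabetes-medication fill or any other diabetes diagnosis; an outpatient
#' diagnosis by a fill or an inpatient diagnosis (any position); a
#' prescription by a diabetes diagnosis, or by a second fill together with a
#' diabetes-management procedure and no absent/irregular-menses diagnosis in
#' the search window. The secondary variant auto-confirms secondary inpatient
#' diagnoses and additionally lets a glycosylated-hemoglobin procedure alone
#' confirm an outpatient diagnosis. Confirming events must be strictly later
#' than the encounter (the prescription pathway's procedure may share a date
#' with the second fill) and at or before `window_end`.
#'
#' @param dataset A `claims_dataset`.
#' @param person_id Person identifier.
#' @param encounter_type One of `"inpatient_primary"`, `"inpatient_secondary"`,
#'   `"outpatient"`, `"prescription"`.
#' @param encounter_date The initial encounter's index date.
#' @param variant `"primary"` or `"secondary"`.
#' @param window_end Last date searched for confirming events.
#' @param registry A `code_registry`.
#' @return List with `confirmed`, `confirmation` (one of `not_required`,
#'   `by_prescription`, `by_diagnosis`, `by_rx_plus_procedure`,
#'   `by_hba1c_procedure`, `none_found`) and `confirmation_date`.
#' @export
confirm_encounter <- function(dataset, person_id, encounter_type,
                              encounter_date, variant = c("primary", "secondary"),
                              window_end, registry = default_registry()) {
  variant <- match.arg(variant)
  pc <- split_claims(dataset)[[person_id]]
  if (is.null(pc)) stop("unknown person_id: ", person_id, call. = FALSE)
  confirm_encounter_for(pc, encounter_type, as_date(encounter_date), registry,
                        variant, as_date(window_end))
}

#' Assign the final index date
#'
#' If at least one diabetes-related procedure falls in `[t_x - 29, t_x - 1]`,
#' the index date is reset to the earliest such procedure (the testing visit
#' that initiated the diagnostic episode); otherwise it stays at `t_x`.
#'
#' @param dataset A `claims_dataset`.
#' @param person_id Person identifier.
#' @param t_x Initial index date.
#' @param registry A `code_registry`.
#' @param config A [phenotype_config()].
#' @return The final index date.
#' @export
assign_final_index <- function(dataset, person_id, t_x,
                               registry = default_registry(),
                               config = phenotype_config()) {
  pc <- split_claims(dataset)[[person_id]]
  if (is.null(pc)) stop("unknown person_id: ", person_id, call. = FALSE)
  assign_final_index_for(pc, as_date(t_x), registry, config)
}

assign_final_index_for <- function(pc, t_x, registry, config) {
  d <- pc$procedures$service_date[
    safe_match(registry$proc_diabetes_related, pc$procedures$procedure_code)]
  d <- d[d >= t_x - config$index_reset_days & d <= t_x - 1]
  if (length(d) > 0L) min(d) else t_x
}

#' Classify diabetes subtype from prescription fills
#'
#' Type 1 when at least one insulin fill falls within 120 days after the
#' final index date and at most one oral-hypoglycemic fill falls in that
#' interval (a single oral agent may be prescribed while type 1 confirmatory
#' testing is pending); otherwise type 2.
#'
#' @param dataset A `claims_dataset`.
#' @param person_id Person identifier.
#' @param final_index Final index date.
#' @param registry A `code_registry`.
#' @param config A [phenotype_config()].
#' @return `"type1"` or `"type2"`.
#' @export
classify_subtype <- function(dataset, person_id, final_index,
                             registry = default_registry(),
                             config = phenotype_config()) {
  pc <- split_claims(dataset)[[person_id]]
  if (is.null(pc)) stop("unknown person_id: ", person_id, call. = FALSE)
  classify_subtype_for(pc, as_date(final_index), registry, config)
}

classify_subtype_for <- function(pc, final_index, registry, config) {
  rx <- pc$prescriptions
  w <- rx$fill_date >= final_index &
    rx$fill_date <= final_index + config$subtype_window_days
  insulin_classes <- registry$drug_insulin
  if (isTRUE(config$adjunct_counts_as_insulin)) {
    insulin_classes <- c(insulin_classes, registry$drug_insulin_adjunct)
  }
  n_insulin <- sum(w & rx$drug_class %in% insulin_classes)
  n_oral <- sum(w & rx$drug_class %in% registry$drug_oral_hypoglycemic)
  if (n_insulin >= 1L && n_oral <= 1L) "type1" else "type2"
}

CASE_RECORD_COLS <- c("person_id", "met_definition", "definition_variant",
                      "initial_index_date", "final_index_date",
                      "encounter_type", "confirmation", "confirmation_date",
                      "excluded_reason", "subtype", "evidence")

# Internal: verdict for one member as a named list (no data-frame overhead).
apply_definition_for <- function(pc, member, registry, variant, config) {
  rec <- list(person_id = member$person_id, met_definition = FALSE,
              definition_variant = variant,
              initial_index_date = as.Date(NA), final_index_date = as.Date(NA),
              encounter_type = NA_character_, confirmation = NA_character_,
              confirmation_date = as.Date(NA), excluded_reason = "none",
              subtype = "not_applicable", evidence = "")
  enc <- extract_encounters_for(pc, member$followup_start, member$followup_end,
                                registry, config)
  n_enc <- length(enc$encounter_type)
  if (n_enc == 0L) return(rec)

  events <- confirmation_events(pc, registry)
  n_try <- if (isTRUE(config$fall_through)) n_enc else 1L

  for (i in seq_len(n_try)) {
    e_type <- enc$encounter_type[i]
    t_x <- enc$event_date[i]
    rec$initial_index_date <- t_x
    rec$encounter_type <- e_type
    rec$evidence <- paste0(e_type, "@", t_x)

    if (e_type != "inpatient_primary" &&
        pcos_excluded_for(pc, t_x, registry, config)) {
      rec$excluded_reason <- "pcos_window"
      rec$confirmation <- NA_character_
      rec$met_definition <- FALSE
      next
    }
    rec$excluded_reason <- "none"
    window_end <- if (is.finite(config$confirmation_window_days)) {
      min(member$followup_end, t_x + config$confirmation_window_days)
    } else {
      member$followup_end
    }
    conf <- confirm_encounter_for(pc, e_type, t_x, registry, variant,
                                  window_end, events)
    rec$confirmation <- conf$confirmation
    rec$confirmation_date <- conf$confirmation_date
    if (!conf$confirmed) {
      rec$met_definition <- FALSE
      next
    }
    rec$met_definition <- TRUE
    rec$final_index_date <- assign_final_index_for(pc, t_x, registry, config)
    rec$subtype <- classify_subtype_for(pc, rec$final_index_date, registry, config)
    rec$evidence <- paste0(
      rec$evidence,
      if (!is.na(conf$confirmation_date)) {
        paste0(";conf=", conf$confirmation, "@", conf$confirmation_date)
      } else {
        paste0(";conf=", conf$confirmation)
      },
      if (rec$final_index_date != t_x) paste0(";reset@", rec$final_index_date) else "",
      ";subtype=", rec$subtype)
    break
  }
  rec
}

case_records_frame <- function(recs) {
  if (length(recs) == 0L) {
    return(data.frame(person_id = character(0), met_definition = logical(0),
                      definition_variant = character(0),
                      initial_index_date = as.Date(character(0)),
                      final_index_date = as.Date(character(0)),
                      encounter_type = character(0), confirmation = character(0),
                      confirmation_date = as.Date(character(0)),
                      excluded_reason = character(0), subtype = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  grab_chr <- function(f) vapply(recs, function(r) r[[f]], character(1))
  grab_lgl <- function(f) vapply(recs, function(r) r[[f]], logical(1))
  grab_date <- function(f) {
    as.Date(vapply(recs, function(r) as.numeric(r[[f]]), numeric(1)),
            origin = "1970-01-01")
  }
  data.frame(person_id = grab_chr("person_id"),
             met_definition = grab_lgl("met_definition"),
             definition_variant = grab_chr("definition_variant"),
             initial_index_date = grab_date("initial_index_date"),
             final_index_date = grab_date("final_index_date"),
             encounter_type = grab_chr("encounter_type"),
             confirmation = grab_chr("confirmation"),
             confirmation_date = grab_date("confirmation_date"),
             excluded_reason = grab_chr("excluded_reason"),
             subtype = grab_chr("subtype"),
             evidence = grab_chr("evidence"),
             stringsAsFactors = FALSE)
}

#' Apply the case definition to one cohort member
#'
#' Takes the first diabetes-related encounter of follow-up; a primary
#' inpatient diagnosis meets the definition immediately, any other encounter
#' passes through the PCOS exclusion window and the confirmation matrix. Met
#' cases receive a final index date and a subtype. By default a failed first
#' encounter settles the verdict (no fall-through to later encounters).
#'
#' @param dataset A `claims_dataset`.
#' @param member One-row data frame (or list) with `person_id`,
#'   `followup_start`, `followup_end` as produced by [build_cohort()].
#' @param registry A `code_registry`.
#' @param variant `"primary"` or `"secondary"`.
#' @param config A [phenotype_config()].
#' @return A one-row case-record data frame: `person_id`, `met_definition`,
#'   `definition_variant`, `initial_index_date`, `final_index_date`,
#'   `encounter_type`, `confirmation`, `confirmation_date`,
#'   `excluded_reason`, `subtype`, `evidence`.
#' @export
apply_definition <- function(dataset, member, registry = default_registry(),
                             variant = c("primary", "secondary"),
                             config = phenotype_config()) {
  variant <- match.arg(variant)
  member <- as.list(member)
  member$followup_start <- as_date(member$followup_start)
  member$followup_end <- as_date(member$followup_end)
  pc <- split_claims(dataset)[[member$person_id]]
  if (is.null(pc)) stop("unknown person_id: ", member$person_id, call. = FALSE)
  case_records_frame(list(
    apply_definition_for(pc, member, registry, variant, config)))
}

#' Classify every cohort member
#'
#' Vectorized driver over [apply_definition()]: one case record per member,
#' met or not.
#'
#' @param dataset A `claims_dataset`.
#' @param cohort Cohort data frame from [build_cohort()] (or the synthetic
#'   generator).
#' @param registry A `code_registry`.
#' @param variant `"primary"` or `"secondary"`.
#' @param config A [phenotype_config()].
#' @return Data frame of case records, one row per cohort member.
#' @export
classify_cohort <- function(dataset, cohort, registry = default_registry(),
                            variant = c("primary", "secondary"),
                            config = phenotype_config()) {
  variant <- match.arg(variant)
  if (nrow(cohort) == 0L) return(case_records_frame(list()))
  by_person <- split_claims(dataset)
  fu_start <- as_date(cohort$followup_start)
  fu_end <- as_date(cohort$followup_end)
  recs <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$person_id[i]
    pc <- by_person[[pid]]
    if (is.null(pc)) {
      stop("cohort member without claims: ", pid, call. = FALSE)
    }
    apply_definition_for(pc, list(person_id = pid, followup_start = fu_start[i],
                                  followup_end = fu_end[i]),
                         registry, variant, config)
  })
  case_records_frame(recs)
}
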
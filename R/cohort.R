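# New-user cohort construction: baseline eligibility (age 6-24, one year of
# continuously covered prior enrollment with lapses of <= 7 days, medical care
# utilization in that year, no prior medical care indicating diabetes, no
# exclusion condition, no hospital discharge in the past 30 days), qualifying
# drug initiation with a 365-day washout and a 90-day post-discharge
# allowance, and follow-up window computation.

#' Engine configuration
#'
#' Bundles the tunable parameters of the cohort builder and case-definition
#' engine. All durations are whole days; intervals are closed.
#'
#' @param study_start,study_end Calendar bounds of the study period.
#' @param min_age Youngest eligible age in completed years (default 6).
#' @param max_age_excl Exclusive upper age bound; eligibility requires age
#'   strictly below this (default 25).
#' @param washout_days Lookback with no study-drug fill required before a
#'   qualifying initiation, and the span of the baseline-enrollment /
#'   prior-diabetes-care checks (default 365).
#' @param initiation_allowance_days Non-qualifying study-drug use in this many
#'   days before the qualifying fill is tolerated (post-discharge starts), as
#'   long as the washout holds before the earliest fill of that cluster
#'   (default 90).
#' @param max_gap_days Longest enrollment lapse still counted as continuous
#'   coverage (default 7).
#' @param recent_hosp_days No hospital discharge may fall within this many
#'   days before cohort entry (default 30).
#' @param days_supplied_default Days of drug supply assumed per fill when the
#'   prescription table carries no `days_supplied` column (default 30).
#' @param grace_days Permissible gap between the end of one fill's supply and
#'   the next fill for the "current use" chain (default 0).
#' @param discontinuation_days Follow-up ends this many days after the last
#'   day of current study-drug use (default 365).
#' @param pcos_window_days Half-width of the polycystic-ovarian-syndrome
#'   exclusion window around a prescription index date (default 120).
#' @param index_reset_days Lookback for resetting the index date to an earlier
#'   diabetes-related procedure (default 29; window is `[t - 29, t - 1]`).
#' @param subtype_window_days Width of the post-index window inspected for
#'   insulin and oral-hypoglycemic fills when classifying subtype
#'   (default 120).
#' @param confirmation_window_days Cap on the confirmation search window in
#'   days after the initial encounter, or `Inf` to search to the end of
#'   follow-up (default `Inf`).
#' @param adjunct_counts_as_insulin Should insulin-adjunct fills count toward
#'   the type-1 insulin requirement? Default `FALSE`.
#' @param fall_through If the first diabetes-related encounter fails
#'   (excluded or unconfirmed), should the engine move on to later
#'   encounters? Default `FALSE`: the verdict rests on the first encounter of
#'   follow-up.
#' @return A `phenotype_config` list.
#' @export
phenotype_config <- function(study_start = as.Date("1996-01-01"),
                             study_end = as.Date("2007-12-31"),
                             min_age = 6L,
                             max_age_excl = 25L,
                             washout_days = 365L,
                             initiation_allowance_days = 90L,
                             max_gap_days = 7L,
                             recent_hosp_days = 30L,
                             days_supplied_default = 30L,
                             grace_days = 0L,
                             discontinuation_days = 365L,
                             pcos_window_days = 120L,
                             index_reset_days = 29L,
                             subtype_window_days = 120L,
                             confirmation_window_days = Inf,
                             adjunct_counts_as_insulin = FALSE,
                             fall_through = FALSE) {
  cfg <- list(study_start = as_date(study_start), study_end = as_date(study_end),
              min_age = min_age, max_age_excl = max_age_excl,
              washout_days = washout_days,
              initiation_allowance_days = initiation_allowance_days,
              max_gap_days = max_gap_days, recent_hosp_days = recent_hosp_days,
              days_supplied_default = days_supplied_default,
              grace_days = grace_days,
              discontinuation_days = discontinuation_days,
              pcos_window_days = pcos_window_days,
              index_reset_days = index_reset_days,
              subtype_window_days = subtype_window_days,
              confirmation_window_days = confirmation_window_days,
              adjunct_counts_as_insulin = adjunct_counts_as_insulin,
              fall_through = fall_through)
  stopifnot(cfg$study_start <= cfg$study_end, cfg$min_age < cfg$max_age_excl)
  structure(cfg, class = "phenotype_config")
}

# Split every claims table by person, returning a list keyed by person_id of
# per-person claim lists. Tables are carried as plain lists of column vectors
# (not data frames): splitting once up front and avoiding data-frame method
# dispatch keeps the per-person engine loops fast on large datasets.
split_claims <- function(dataset) {
  ids <- dataset$persons$person_id
  tabs <- c("inpatient", "outpatient", "prescriptions", "procedures",
            "enrollment", "exclusion_flags")
  by_tab <- lapply(tabs, function(nm) {
    tbl <- dataset[[nm]]
    idx <- split(seq_len(nrow(tbl)), factor(tbl$person_id, levels = ids))
    cols <- as.list(tbl)
    lapply(idx, function(ii) lapply(cols, function(col) col[ii]))
  })
  names(by_tab) <- tabs
  pcols <- as.list(dataset$persons)
  out <- lapply(seq_along(ids), function(i) {
    pc <- lapply(by_tab, function(s) s[[i]])
    pc$person <- lapply(pcols, function(col) col[i])
    pc
  })
  names(out) <- ids
  out
}

# number of claims in a per-person table (list of equal-length columns)
n_claims <- function(tab) length(tab[[1]])

# All dates on which the person carries a diagnosis matching `patterns`, in
# any position, inpatient or outpatient.
dx_match_dates <- function(pc, patterns, settings = NULL) {
  dates <- list()
  ov <- pc$outpatient
  keep <- if (is.null(settings)) TRUE else ov$setting %in% settings
  if (n_claims(ov) > 0L) {
    hit <- keep & (safe_match(patterns, ov$primary_dx) |
                     multi_dx_match(patterns, ov$secondary_dx))
    dates[[1]] <- ov$visit_date[hit]
  }
  ip <- pc$inpatient
  if (n_claims(ip) > 0L) {
    hit <- safe_match(patterns, ip$primary_dx) |
      multi_dx_match(patterns, ip$secondary_dx) |
      multi_dx_match(patterns, ip$admission_dx)
    dates[[2]] <- ip$admission_date[hit]
  }
  if (length(dates) == 0L) return(as.Date(character(0)))
  do.call(c, dates)
}

# Vectorized match over semicolon-delimited multi-code cells.
multi_dx_match <- function(patterns, cells) {
  if (length(cells) == 0L) return(logical(0))
  out <- logical(length(cells))
  has <- !is.na(cells) & nzchar(cells)
  if (any(has)) {
    parts <- strsplit(cells[has], ";", fixed = TRUE)
    out[has] <- vapply(parts, function(cc) {
      cc <- cc[nzchar(cc)]
      length(cc) > 0L && any(match_code(patterns, cc))
    }, logical(1))
  }
  out
}

diabetes_drug_classes <- function(registry) {
  c(registry$drug_insulin, registry$drug_insulin_adjunct,
    registry$drug_oral_hypoglycemic)
}

# Baseline eligibility on one candidate date, for one person's claims.
eligibility_reasons <- function(pc, candidate_date, registry, config) {
  reasons <- character(0)
  cd <- candidate_date
  age <- age_on(pc$person$birth_date, cd)
  if (is.na(age) || age < config$min_age || age >= config$max_age_excl) {
    reasons <- c(reasons, "age")
  }
  norm <- normalize_enrollment(pc$enrollment, config$max_gap_days)
  if (nrow(norm) == 0L || !covers_interval(norm, cd - config$washout_days, cd)) {
    reasons <- c(reasons, "enrollment_gap")
  }
  util_dates <- c(pc$inpatient$admission_date, pc$outpatient$visit_date,
                  pc$prescriptions$fill_date, pc$procedures$service_date)
  if (!any(util_dates >= cd - config$washout_days & util_dates <= cd - 1)) {
    reasons <- c(reasons, "no_utilization")
  }
  dm_dx <- dx_match_dates(pc, registry$dx_diabetes_general)
  dm_rx <- pc$prescriptions$fill_date[
    pc$prescriptions$drug_class %in% diabetes_drug_classes(registry)]
  if (any(dm_dx <= cd) || any(dm_rx <= cd)) {
    reasons <- c(reasons, "prior_diabetes_care")
  }
  xf <- pc$exclusion_flags
  if (n_claims(xf) > 0L) {
    active <- xf$start_date <= cd & xf$end_date >= cd
    if (any(active)) {
      reasons <- c(reasons, paste0("exclusion_flag:", sort(unique(xf$flag[active]))))
    }
  }
  disch <- pc$inpatient$discharge_date
  if (any(disch >= cd - config$recent_hosp_days & disch <= cd - 1)) {
    reasons <- c(reasons, "recent_hospitalization")
  }
  reasons
}

#' Check baseline cohort eligibility on a candidate date
#'
#' A person is eligible on a date when: age is within `[6, 25)` years; the
#' full year before the date is covered by enrollment (lapses of at most 7
#' days tolerated) and contains at least one medical care claim; no diagnosis
#' of diabetes or fill of a diabetes medication has occurred on or before the
#' date; no exclusion condition (life-threatening illness, institutional
#' residence, schizophrenia/psychosis, pregnancy, PCOS) is active; and no
#' hospital discharge falls in the preceding 30 days.
#'
#' @param dataset A `claims_dataset`.
#' @param person_id Person identifier.
#' @param candidate_date Date to test.
#' @param registry A `code_registry`.
#' @param config A [phenotype_config()].
#' @return List with `eligible` (logical) and `reasons` (character vector of
#'   failed criteria, empty when eligible).
#' @export
check_baseline_eligibility <- function(dataset, person_id, candidate_date,
                                       registry = default_registry(),
                                       config = phenotype_config()) {
  idx <- match(person_id, dataset$persons$person_id)
  if (is.na(idx)) stop("unknown person_id: ", person_id, call. = FALSE)
  pc <- split_claims(dataset)[[person_id]]
  reasons <- eligibility_reasons(pc, as_date(candidate_date), registry, config)
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

# First qualifying initiation of a study drug, or NULL. Washout rule: a fill
# qualifies when the preceding 365 days contain no study-drug fill, or when
# every such fill lies within the 90 days before it (a post-discharge start)
# and the earliest fill of that cluster itself has a clean 365-day washout.
find_qualifying_fill <- function(pc, registry, config) {
  rx <- pc$prescriptions
  study_fills <- sort(unique(rx$fill_date[rx$drug_class == "study_psychotropic"]))
  if (length(study_fills) == 0L) return(NULL)
  for (f in seq_along(study_fills)) {
    F <- study_fills[f]
    prior <- study_fills[study_fills >= F - config$washout_days & study_fills < F]
    if (length(prior) > 0L) {
      within_allowance <- all(prior >= F - config$initiation_allowance_days)
      if (!within_allowance) next
      E <- min(prior)
      pre_cluster <- study_fills[study_fills >= E - config$washout_days &
                                   study_fills < E]
      if (length(pre_cluster) > 0L) next
    }
    if (length(eligibility_reasons(pc, F, registry, config)) == 0L) {
      return(F)
    }
  }
  NULL
}

# Follow-up end for one member: minimum of study end, day before the 25th
# birthday, disenrollment, criteria failure (an exclusion flag turning on),
# and 365 days after the last day of current study-drug use.
followup_end_for <- function(pc, qualifying_fill_date, config) {
  fstart <- qualifying_fill_date + 1
  cand <- list()
  cand$study_end <- config$study_end
  cand$age_25 <- nth_birthday(pc$person$birth_date, config$max_age_excl) - 1
  norm <- normalize_enrollment(pc$enrollment, config$max_gap_days)
  spell <- norm[norm$start_date <= fstart & norm$end_date >= fstart, , drop = FALSE]
  cand$disenrollment <- if (nrow(spell) > 0L) spell$end_date[1] else fstart
  xf <- pc$exclusion_flags
  if (n_claims(xf) > 0L) {
    onset <- xf$start_date[xf$start_date >= fstart]
    if (length(onset) > 0L) cand$criteria_failure <- min(onset) - 1
  }
  rx <- pc$prescriptions
  sel <- rx$drug_class == "study_psychotropic" &
    rx$fill_date >= qualifying_fill_date
  fills <- rx$fill_date[sel]
  supply <- if ("days_supplied" %in% names(rx)) {
    s <- suppressWarnings(as.numeric(rx$days_supplied[sel]))
    ifelse(is.na(s), config$days_supplied_default, s)
  } else {
    rep(config$days_supplied_default, length(fills))
  }
  ord <- order(fills)
  fills <- fills[ord]
  supply <- supply[ord]
  use_end <- fills[1] + supply[1]
  if (length(fills) > 1L) {
    for (i in 2:length(fills)) {
      if (fills[i] <= use_end + config$grace_days) {
        use_end <- max(use_end, fills[i] + supply[i])
      } else {
        break
      }
    }
  }
  cand$drug_discontinuation_365 <- use_end + config$discontinuation_days

  dates <- do.call(c, cand)
  # fixed priority resolves ties toward administrative bounds
  priority <- c("study_end", "age_25", "disenrollment", "criteria_failure",
                "drug_discontinuation_365")
  ord <- order(dates, match(names(cand), priority))
  list(followup_end = dates[[ord[1]]], censor_reason = names(cand)[ord[1]])
}

#' Compute a cohort member's follow-up end date
#'
#' Follow-up runs from the day after the qualifying fill to the earliest of:
#' the study end, the day before the 25th birthday, disenrollment, failure of
#' an inclusion/exclusion criterion, and 365 days after the last day of
#' current study-drug use (fill date plus days supplied, chained across
#' refills).
#'
#' @inheritParams check_baseline_eligibility
#' @param qualifying_fill_date The member's qualifying study-drug fill date.
#' @return List with `followup_end` (Date) and `censor_reason`.
#' @export
compute_followup_end <- function(dataset, person_id, qualifying_fill_date,
                                 config = phenotype_config()) {
  pc <- split_claims(dataset)[[person_id]]
  if (is.null(pc)) stop("unknown person_id: ", person_id, call. = FALSE)
  followup_end_for(pc, as_date(qualifying_fill_date), config)
}

#' Build the new-user study cohort
#'
#' Scans every person for their first qualifying study-drug initiation on a
#' day of full baseline eligibility and derives the follow-up window. At most
#' one cohort entry per person.
#'
#' @param dataset A `claims_dataset`.
#' @param registry A `code_registry`.
#' @param config A [phenotype_config()].
#' @return Data frame with one row per cohort member: `person_id`,
#'   `time_zero`, `qualifying_fill_date`, `followup_start`, `followup_end`,
#'   `censor_reason`. Members whose follow-up closes before it opens are
#'   dropped.
#' @export
build_cohort <- function(dataset, registry = default_registry(),
                         config = phenotype_config()) {
  by_person <- split_claims(dataset)
  ids <- character(0)
  tzero <- fu_end <- as.Date(character(0))
  reason <- character(0)
  for (pc in by_person) {
    F <- find_qualifying_fill(pc, registry, config)
    if (is.null(F)) next
    fu <- followup_end_for(pc, F, config)
    ids <- c(ids, pc$person$person_id)
    tzero <- c(tzero, F)
    fu_end <- c(fu_end, fu$followup_end)
    reason <- c(reason, fu$censor_reason)
  }
  out <- data.frame(person_id = ids, time_zero = tzero,
                    qualifying_fill_date = tzero, followup_start = tzero + 1,
                    followup_end = fu_end, censor_reason = reason,
                    stringsAsFactors = FALSE)
  out <- out[out$followup_end >= out$followup_start, , drop = FALSE]
  rownames(out) <- NULL
  out
}
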
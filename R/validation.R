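# Validation statistics for a case definition against adjudicated labels:
# positive predictive value with Wilson score intervals, design-weighted
# sensitivity/specificity under partial adjudication, and contingency
# reports crossing engine verdicts with adjudication categories.

ADJUDICATION_STATUSES <- c("incident_diabetes", "prevalent_diabetes",
                           "possible_diabetes", "subthreshold_hyperglycemia",
                           "pcos", "lab_rule_out", "miscoded",
                           "not_diabetes_other")

#' Positive predictive value
#'
#' Among adjudicated persons flagged by the definition, the fraction
#' confirmed as true incident cases by record review.
#'
#' @param confirmed Number adjudicated as true cases.
#' @param adjudicated_total Number flagged and adjudicated.
#' @return Proportion in `[0, 1]`.
#' @export
ppv <- function(confirmed, adjudicated_total) {
  if (adjudicated_total <= 0) {
    stop("undefined estimate: no adjudicated cases (denominator is 0)",
         call. = FALSE)
  }
  stopifnot(confirmed >= 0, confirmed <= adjudicated_total)
  confirmed / adjudicated_total
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Center \eqn{(\hat p + z^2/2n) / (1 + z^2/n)}, half-width
#' \eqn{[z/(1 + z^2/n)] \sqrt{\hat p (1-\hat p)/n + z^2/4n^2}}. Better
#' small-sample coverage than the Wald interval; never leaves `[0, 1]`.
#'
#' @param successes Number of successes (vectorized).
#' @param n Number of trials.
#' @param z Standard-normal quantile (default 1.959964, two-sided 95%).
#' @return Data frame with columns `lower` and `upper`.
#' @export
#' @examples
#' wilson_ci(41, 46)
wilson_ci <- function(successes, n, z = 1.959964) {
  if (any(n <= 0)) stop("undefined estimate: n must be positive", call. = FALSE)
  stopifnot(all(successes >= 0), all(successes <= n), z > 0)
  p_hat <- successes / n
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))
  lower <- pmax(0, center - half)
  upper <- pmin(1, center + half)
  # algebraic identities at the boundary (guard against rounding drift)
  lower[successes == 0] <- 0
  upper[successes == n] <- 1
  data.frame(lower = lower, upper = upper)
}

#' Bundle the counts feeding the sensitivity/specificity estimators
#'
#' The catchment contains `n_meeting` persons flagged by the definition and
#' `n_not_meeting` persons with other diabetes-related encounters; of each
#' group a subset was adjudicated and a subset of those adjudicated were true
#' incident cases.
#'
#' @param n_meeting Flagged persons in the catchment.
#' @param n_meeting_adjudicated Flagged persons adjudicated.
#' @param n_meeting_true Flagged, adjudicated, confirmed true.
#' @param n_not_meeting Non-flagged persons with diabetes-related encounters.
#' @param n_not_meeting_adjudicated Of those, adjudicated.
#' @param n_not_meeting_true Of those adjudicated, true cases.
#' @param n_noncases_denominator Estimated count of catchment persons without
#'   the condition, required for specificity (optional).
#' @param z Standard-normal quantile for intervals (default 1.959964).
#' @return A `validation_cells` list.
#' @export
validation_cells <- function(n_meeting, n_meeting_adjudicated, n_meeting_true,
                             n_not_meeting, n_not_meeting_adjudicated,
                             n_not_meeting_true, n_noncases_denominator = NULL,
                             z = 1.959964) {
  cells <- list(n_meeting = n_meeting,
                n_meeting_adjudicated = n_meeting_adjudicated,
                n_meeting_true = n_meeting_true,
                n_not_meeting = n_not_meeting,
                n_not_meeting_adjudicated = n_not_meeting_adjudicated,
                n_not_meeting_true = n_not_meeting_true,
                n_noncases_denominator = n_noncases_denominator,
                z = z)
  counts <- unlist(cells[1:6])
  stopifnot(all(counts >= 0),
            n_meeting_true <= n_meeting_adjudicated,
            n_meeting_adjudicated <= n_meeting,
            n_not_meeting_true <= n_not_meeting_adjudicated,
            n_not_meeting_adjudicated <= n_not_meeting)
  structure(cells, class = "validation_cells")
}

#' Design-weighted sensitivity estimate
#'
#' Sensitivity is `a / (a + c)`: `a`, the number of true cases found, is the
#' flagged catchment count scaled by the adjudicated positive predictive
#' value; `c`, the number missed, is the non-flagged encounter count scaled
#' by the adjudicated true-case proportion in that stratum.
#'
#' @param cells A [validation_cells()] object.
#' @return Proportion in `[0, 1]`.
#' @export
estimate_sensitivity <- function(cells) {
  stopifnot(inherits(cells, "validation_cells"))
  if (cells$n_meeting_adjudicated <= 0 || cells$n_not_meeting_adjudicated <= 0) {
    stop("undefined estimate: both strata need adjudicated cases", call. = FALSE)
  }
  a <- cells$n_meeting * (cells$n_meeting_true / cells$n_meeting_adjudicated)
  c_ <- cells$n_not_meeting *
    (cells$n_not_meeting_true / cells$n_not_meeting_adjudicated)
  if (a + c_ == 0) {
    stop("undefined estimate: no true cases in either stratum", call. = FALSE)
  }
  a / (a + c_)
}

#' Design-weighted specificity estimate
#'
#' Specificity is `d / (b + d)`: `b`, the flagged false positives, is the
#' flagged catchment count times one minus the positive predictive value;
#' `d` is the non-case denominator less `b`.
#'
#' @param cells A [validation_cells()] object with `n_noncases_denominator`.
#' @return Proportion in `[0, 1]`.
#' @export
estimate_specificity <- function(cells) {
  stopifnot(inherits(cells, "validation_cells"))
  if (is.null(cells$n_noncases_denominator)) {
    stop("specificity needs n_noncases_denominator (catchment non-case count)",
         call. = FALSE)
  }
  if (cells$n_meeting_adjudicated <= 0) {
    stop("undefined estimate: no adjudicated flagged cases", call. = FALSE)
  }
  p <- cells$n_meeting_true / cells$n_meeting_adjudicated
  b <- cells$n_meeting * (1 - p)
  d <- cells$n_noncases_denominator - b
  d / (b + d)
}

join_labels <- function(cases, labels) {
  idx <- match(cases$person_id, labels$person_id)
  miss <- is.na(idx) & cases$met_definition
  cases$adjudicated_status <- labels$adjudicated_status[idx]
  cases$adjudicated_subtype <- labels$adjudicated_subtype[idx]
  cases
}

count_row <- function(status_vec, subtype_vec, status, subtype = NULL) {
  if (is.null(subtype)) {
    sum(status_vec %in% status, na.rm = TRUE)
  } else {
    sum(status_vec %in% status & subtype_vec %in% subtype, na.rm = TRUE)
  }
}

#' Contingency report of engine verdicts against adjudication
#'
#' Produces two tables: (1) for adjudicated persons meeting the definition, a
#' cross of engine subtype (any / type 1 / type 2) against adjudicated status
#' and subtype; (2) for adjudicated persons not meeting it, a cross of
#' adjudicated status against the type of the index encounter. Percentages
#' are column percentages of the adjudicated total, printed to one decimal
#' (half-up).
#'
#' @param cases Case-record data frame (needs `person_id`, `met_definition`,
#'   `subtype`, `encounter_type`).
#' @param labels Adjudication-label data frame (`person_id`,
#'   `adjudicated_status`, `adjudicated_subtype`); persons without a label are
#'   treated as not adjudicated.
#' @return A `dm_validation_report`: list with data frames `meeting` and
#'   `not_meeting`, each carrying counts and percentages.
#' @export
contingency_report <- function(cases, labels) {
  bad <- !labels$person_id %in% cases$person_id
  if (any(bad)) {
    stop("adjudication labels without matching case records: ",
         paste(utils::head(labels$person_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  cases <- join_labels(cases, labels)

  meeting <- cases[cases$met_definition & !is.na(cases$adjudicated_status), ,
                   drop = FALSE]
  cols <- list(any = rep(TRUE, nrow(meeting)),
               type1 = meeting$subtype == "type1",
               type2 = meeting$subtype == "type2")
  status_rows <- list(
    adjudicated_total = ADJUDICATION_STATUSES,
    incident_diabetes = "incident_diabetes",
    incident_type1 = list("incident_diabetes", "type1"),
    incident_type2 = list("incident_diabetes", "type2"),
    incident_unspecified = list("incident_diabetes", "unspecified"),
    not_incident = setdiff(ADJUDICATION_STATUSES, "incident_diabetes"),
    prevalent_diabetes = "prevalent_diabetes",
    subthreshold_hyperglycemia = "subthreshold_hyperglycemia",
    pcos = "pcos",
    possible_diabetes = "possible_diabetes",
    lab_rule_out = "lab_rule_out",
    miscoded = "miscoded",
    not_diabetes_other = "not_diabetes_other")
  mk_tbl <- function(sel_list, status_vec, subtype_vec) {
    out <- data.frame(row = names(status_rows), stringsAsFactors = FALSE)
    for (cn in names(sel_list)) {
      sel <- sel_list[[cn]]
      sv <- status_vec[sel]
      tv <- subtype_vec[sel]
      denom <- length(sv)
      n <- vapply(status_rows, function(spec) {
        if (is.list(spec)) {
          count_row(sv, tv, spec[[1]], spec[[2]])
        } else {
          count_row(sv, tv, spec)
        }
      }, numeric(1))
      out[[paste0(cn, "_n")]] <- n
      out[[paste0(cn, "_pct")]] <- if (denom > 0) {
        round_half_up(100 * n / denom, 1)
      } else {
        rep(NA_real_, length(n))
      }
    }
    out
  }
  meeting_tbl <- mk_tbl(cols, meeting$adjudicated_status,
                        meeting$adjudicated_subtype)

  nm <- cases[!cases$met_definition & !is.na(cases$adjudicated_status), ,
              drop = FALSE]
  enc_cols <- list(inpatient_secondary = nm$encounter_type == "inpatient_secondary",
                   outpatient = nm$encounter_type == "outpatient",
                   prescription = nm$encounter_type == "prescription",
                   any = rep(TRUE, nrow(nm)))
  nm_rows <- list(
    adjudicated_total = ADJUDICATION_STATUSES,
    incident_diabetes = "incident_diabetes",
    not_incident = setdiff(ADJUDICATION_STATUSES, "incident_diabetes"),
    prevalent_diabetes = "prevalent_diabetes",
    possible_diabetes = "possible_diabetes",
    subthreshold_hyperglycemia = "subthreshold_hyperglycemia",
    pcos = "pcos",
    lab_rule_out = "lab_rule_out",
    miscoded = "miscoded",
    not_diabetes_other = "not_diabetes_other")
  status_rows <- nm_rows
  not_meeting_tbl <- mk_tbl(enc_cols, nm$adjudicated_status,
                            nm$adjudicated_subtype)

  structure(list(meeting = meeting_tbl, not_meeting = not_meeting_tbl),
            class = "dm_validation_report")
}

#' @export
print.dm_validation_report <- function(x, ...) {
  cat("Adjudication of encounters meeting the definition\n")
  print(x$meeting, row.names = FALSE)
  cat("\nAdjudication of encounters not meeting the definition\n")
  print(x$not_meeting, row.names = FALSE)
  invisible(x)
}

#' Summary validation metrics for one definition variant
#'
#' Computes the PPV strata (overall, engine type 1, engine type 2, type 2
#' with unspecified-type adjudications counted as type 2) with Wilson
#' intervals, the design-weighted sensitivity, and -- when a non-case
#' denominator is supplied -- the specificity.
#'
#' @param cases Case-record data frame for the catchment.
#' @param labels Adjudication labels (persons absent from `labels` count as
#'   not adjudicated).
#' @param n_noncases_denominator Optional catchment non-case count for
#'   specificity.
#' @param z Standard-normal quantile for intervals.
#' @return Data frame with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate`, `ci_lower`, `ci_upper` (estimates as
#'   proportions).
#' @export
validation_metrics <- function(cases, labels, n_noncases_denominator = NULL,
                               z = 1.959964) {
  cases <- join_labels(cases, labels)
  met <- cases[cases$met_definition, , drop = FALSE]
  met_adj <- met[!is.na(met$adjudicated_status), , drop = FALSE]
  nmet <- cases[!cases$met_definition, , drop = FALSE]
  nmet_adj <- nmet[!is.na(nmet$adjudicated_status), , drop = FALSE]

  strata <- list(
    ppv_overall = met_adj,
    ppv_type1 = met_adj[met_adj$subtype == "type1", , drop = FALSE],
    ppv_type2 = met_adj[met_adj$subtype == "type2", , drop = FALSE])
  rows <- lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    num <- if (nm == "ppv_type1") {
      sum(s$adjudicated_status == "incident_diabetes" &
            s$adjudicated_subtype == "type1")
    } else if (nm == "ppv_type2") {
      sum(s$adjudicated_status == "incident_diabetes" &
            s$adjudicated_subtype == "type2")
    } else {
      sum(s$adjudicated_status == "incident_diabetes")
    }
    den <- nrow(s)
    if (den == 0L) {
      return(data.frame(metric = nm, numerator = num, denominator = den,
                        estimate = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, stringsAsFactors = FALSE))
    }
    ci <- wilson_ci(num, den, z)
    data.frame(metric = nm, numerator = num, denominator = den,
               estimate = num / den, ci_lower = ci$lower, ci_upper = ci$upper,
               stringsAsFactors = FALSE)
  })
  # type 2 with unspecified adjudicated subtype counted as type 2
  s <- strata$ppv_type2
  num <- sum(s$adjudicated_status == "incident_diabetes" &
               s$adjudicated_subtype %in% c("type2", "unspecified"))
  den <- nrow(s)
  rows[[length(rows) + 1L]] <- if (den > 0L) {
    ci <- wilson_ci(num, den, z)
    data.frame(metric = "ppv_type2_plus_unspecified", numerator = num,
               denominator = den, estimate = num / den, ci_lower = ci$lower,
               ci_upper = ci$upper, stringsAsFactors = FALSE)
  } else {
    data.frame(metric = "ppv_type2_plus_unspecified", numerator = num,
               denominator = den, estimate = NA_real_, ci_lower = NA_real_,
               ci_upper = NA_real_, stringsAsFactors = FALSE)
  }

  sens <- NA_real_
  if (nrow(met_adj) > 0L && nrow(nmet_adj) > 0L) {
    cells <- validation_cells(
      n_meeting = nrow(met),
      n_meeting_adjudicated = nrow(met_adj),
      n_meeting_true = sum(met_adj$adjudicated_status == "incident_diabetes"),
      n_not_meeting = nrow(nmet),
      n_not_meeting_adjudicated = nrow(nmet_adj),
      n_not_meeting_true = sum(nmet_adj$adjudicated_status == "incident_diabetes"),
      n_noncases_denominator = n_noncases_denominator, z = z)
    sens <- tryCatch(estimate_sensitivity(cells), error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "sensitivity",
      numerator = cells$n_meeting_true, denominator = cells$n_meeting_adjudicated,
      estimate = sens, ci_lower = NA_real_, ci_upper = NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(n_noncases_denominator)) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "specificity", numerator = NA_real_,
        denominator = n_noncases_denominator,
        estimate = estimate_specificity(cells), ci_lower = NA_real_,
        ci_upper = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
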
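# Pipeline drivers: end-to-end run (simulate -> cohort -> classify ->
# validate) with artifacts on disk, and the reference validation report
# recomputed from the packaged person-level reconstruction of the original
# validation sample's adjudication counts.

#' Load the packaged reference validation sample
#'
#' The package ships a person-level reconstruction of the validation sample
#' of the original chart-review study of this case definition: 64 persons
#' meeting the primary definition (46 adjudicated) and 187 persons with other
#' diabetes-related encounters (113 sampled, 30 adjudicated), with their
#' adjudicated statuses and subtypes. Counts, not identities: rows are
#' synthetic person stubs carrying the published cell counts.
#'
#' @return List with data frames `meeting` and `not_meeting`.
#' @export
reference_validation_data <- function() {
  read_fix <- function(file) {
    utils::read.csv(system.file("extdata", file, package = "dmphenotype",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE, na.strings = "")
  }
  list(meeting = read_fix("reference_meeting.csv"),
       not_meeting = read_fix("reference_not_meeting.csv"))
}

# Turn the fixture strata into (cases, labels) pairs for the validation
# module.
reference_cases_labels <- function(ref = reference_validation_data()) {
  m <- ref$meeting
  nm <- ref$not_meeting
  cases <- data.frame(
    person_id = c(m$person_id, nm$person_id),
    met_definition = c(rep(TRUE, nrow(m)), rep(FALSE, nrow(nm))),
    subtype = c(m$computer_subtype, rep("not_applicable", nrow(nm))),
    encounter_type = c(rep(NA_character_, nrow(m)), nm$encounter_type),
    stringsAsFactors = FALSE)
  adj <- rbind(
    m[m$adjudicated == "yes", c("person_id", "adjudicated_status",
                                "adjudicated_subtype")],
    nm[nm$adjudicated == "yes", c("person_id", "adjudicated_status",
                                  "adjudicated_subtype")])
  list(cases = cases, labels = adj,
       n_sampled_not_meeting = sum(nm$sampled == "yes"))
}

#' Reference validation report
#'
#' Recomputes, from the packaged reference sample, every summary statistic of
#' the validation design: positive predictive values (overall, by engine
#' subtype, and with unspecified-type adjudications folded into type 2) with
#' Wilson 95% intervals, the design-weighted sensitivity, the adjudication
#' and sampling fractions, and the contingency tables.
#'
#' @param n_noncases_denominator Optional catchment non-case count enabling
#'   the specificity estimate.
#' @return List with `metrics` (data frame), `report` (a
#'   `dm_validation_report`), and `fractions` (named vector with the
#'   adjudicated-of-meeting and sampled-of-not-meeting proportions).
#' @export
reference_validation_report <- function(n_noncases_denominator = NULL) {
  rcl <- reference_cases_labels()
  metrics <- validation_metrics(rcl$cases, rcl$labels,
                                n_noncases_denominator = n_noncases_denominator)
  report <- contingency_report(rcl$cases, rcl$labels)
  n_meeting <- sum(rcl$cases$met_definition)
  n_meeting_adj <- sum(rcl$labels$person_id %in%
                         rcl$cases$person_id[rcl$cases$met_definition])
  n_not_meeting <- sum(!rcl$cases$met_definition)
  fractions <- c(
    adjudicated_of_meeting = n_meeting_adj / n_meeting,
    sampled_of_not_meeting = rcl$n_sampled_not_meeting / n_not_meeting)
  list(metrics = metrics, report = report, fractions = fractions)
}

format_report_lines <- function(report) {
  fmt_tbl <- function(tbl, col_names) {
    ncols <- (ncol(tbl) - 1L) / 2L
    header <- sprintf("%-28s %s", "", paste(sprintf("%-22s", col_names),
                                            collapse = ""))
    lines <- vapply(seq_len(nrow(tbl)), function(i) {
      cells <- vapply(seq_len(ncols), function(j) {
        n <- tbl[[2L * j]][i]
        pct <- tbl[[2L * j + 1L]][i]
        if (is.na(pct)) sprintf("%-22s", sprintf("%d (--)", n))
        else sprintf("%-22s", sprintf("%d (%.1f)", n, pct))
      }, character(1))
      sprintf("%-28s %s", tbl$row[i], paste(cells, collapse = ""))
    }, character(1))
    c(header, lines)
  }
  c("Adjudication status, encounters meeting the definition",
    fmt_tbl(report$meeting, c("any", "computer type 1", "computer type 2")),
    "",
    "Adjudication status, encounters not meeting the definition",
    fmt_tbl(report$not_meeting,
            c("inpatient secondary", "outpatient", "prescription", "any")))
}

#' Run the full pipeline on synthetic data
#'
#' Generates a seeded synthetic claims population, rebuilds the cohort with
#' the cohort builder, classifies every member under both definition
#' variants, evaluates both against the planted adjudication labels, and
#' writes `cohort.csv`, `cases_primary.csv`, `cases_secondary.csv`,
#' `validation_metrics.csv`, `validation_report.txt` and `manifest.txt` into
#' `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim_config A [scenario_config()].
#' @param registry A `code_registry`.
#' @param config A [phenotype_config()].
#' @param use_generator_cohort Use the generator's own cohort windows instead
#'   of re-deriving them with [build_cohort()] (faster; default `FALSE`).
#' @return Invisibly, a list with the in-memory artifacts (`cohort`, `cases`,
#'   `metrics`).
#' @export
run_pipeline <- function(out_dir, sim_config = scenario_config(n_persons = 200L),
                         registry = default_registry(),
                         config = phenotype_config(),
                         use_generator_cohort = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_claims(sim_config)
  cohort <- if (use_generator_cohort) {
    sim$cohort
  } else {
    build_cohort(sim$dataset, registry, config)
  }
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)

  metrics_all <- list()
  cases_by_variant <- list()
  for (variant in c("primary", "secondary")) {
    cases <- classify_cohort(sim$dataset, cohort, registry, variant, config)
    cases_by_variant[[variant]] <- cases
    utils::write.csv(cases, file.path(out_dir, sprintf("cases_%s.csv", variant)),
                     row.names = FALSE)
    labels <- sim$labels[sim$labels$person_id %in% cases$person_id, ,
                         drop = FALSE]
    m <- validation_metrics(cases, labels)
    m$variant <- variant
    metrics_all[[variant]] <- m
    if (variant == "primary") {
      report <- contingency_report(cases, labels)
      writeLines(format_report_lines(report),
                 file.path(out_dir, "validation_report.txt"))
    }
  }
  metrics <- do.call(rbind, metrics_all)
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(out_dir, "validation_metrics.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("dmphenotype %s",
                       as.character(utils::packageVersion("dmphenotype"))),
               sprintf("seed: %d", sim_config$seed),
               sprintf("n_persons: %d", sim_config$n_persons),
               sprintf("scenario_mix: %s",
                       paste(sprintf("%s=%.3f", names(sim_config$scenario_mix),
                                     sim_config$scenario_mix), collapse = " ")),
               sprintf("generated: %s cohort members, %d classified",
                       nrow(cohort), nrow(cases_by_variant$primary))),
             file.path(out_dir, "manifest.txt"))
  invisible(list(cohort = cohort, cases = cases_by_variant, metrics = metrics))
}
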
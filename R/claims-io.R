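# Claims data model: typed tables for persons, enrollment spells, inpatient
# stays, outpatient visits, prescription fills and procedure claims, with
# delimited-file readers/writers. Rows failing type or invariant checks are
# collected into a rejects report, never silently dropped.

CLAIMS_FILES <- c(persons = "persons.csv", enrollment = "enrollment.csv",
                  inpatient = "inpatient.csv", outpatient = "outpatient.csv",
                  prescriptions = "prescriptions.csv", procedures = "procedures.csv")

DRUG_CLASSES <- c("insulin", "insulin_adjunct", "oral_hypoglycemic",
                  "study_psychotropic", "other")
OUTPATIENT_SETTINGS <- c("outpatient", "emergency", "physician_inpatient")
EXCLUSION_FLAGS <- c("life_threatening_illness", "institutional_residence",
                     "schizophrenia_psychosis", "pregnancy", "pcos")

empty_tbl <- function(spec) {
  cols <- lapply(spec, function(type) {
    switch(type,
           chr = character(0),
           date = as.Date(character(0)),
           num = numeric(0))
  })
  as.data.frame(cols, stringsAsFactors = FALSE, col.names = names(spec))
}

CLAIMS_SCHEMA <- list(
  persons = c(person_id = "chr", birth_date = "date", sex = "chr"),
  enrollment = c(person_id = "chr", start_date = "date", end_date = "date"),
  inpatient = c(person_id = "chr", admission_date = "date", discharge_date = "date",
                primary_dx = "chr", secondary_dx = "chr", admission_dx = "chr"),
  outpatient = c(person_id = "chr", visit_date = "date", primary_dx = "chr",
                 secondary_dx = "chr", setting = "chr"),
  prescriptions = c(person_id = "chr", fill_date = "date", drug_class = "chr",
                    drug_name = "chr"),
  procedures = c(person_id = "chr", service_date = "date", procedure_code = "chr"),
  exclusion_flags = c(person_id = "chr", flag = "chr", start_date = "date",
                      end_date = "date")
)

#' Assemble a claims dataset from its component tables
#'
#' Builds the container the rest of the engine consumes. Any table may be
#' omitted (an empty table of the right shape is substituted). Multi-valued
#' diagnosis columns (`secondary_dx`, `admission_dx`) hold semicolon-delimited
#' code strings within one cell.
#'
#' @param persons,enrollment,inpatient,outpatient,prescriptions,procedures,exclusion_flags
#'   Data frames following the documented column layout (see
#'   [read_claims()]), or `NULL`.
#' @param validate Run invariant checks and move failing rows to the rejects
#'   report (default `TRUE`).
#' @return A `claims_dataset`: a named list of typed data frames with a
#'   `rejects` attribute (data frame with columns `table`, `row`, `reason`).
#' @export
claims_dataset <- function(persons = NULL, enrollment = NULL, inpatient = NULL,
                           outpatient = NULL, prescriptions = NULL,
                           procedures = NULL, exclusion_flags = NULL,
                           validate = TRUE) {
  tables <- list(persons = persons, enrollment = enrollment,
                 inpatient = inpatient, outpatient = outpatient,
                 prescriptions = prescriptions, procedures = procedures,
                 exclusion_flags = exclusion_flags)
  out <- list()
  for (nm in names(CLAIMS_SCHEMA)) {
    spec <- CLAIMS_SCHEMA[[nm]]
    tb <- tables[[nm]]
    if (is.null(tb)) {
      tb <- empty_tbl(spec)
    } else {
      tb <- as.data.frame(tb, stringsAsFactors = FALSE)
      missing_cols <- setdiff(names(spec), names(tb))
      for (mc in missing_cols) tb[[mc]] <- empty_tbl(spec[mc])[[1]][rep(NA, nrow(tb))]
      for (cn in names(spec)) {
        tb[[cn]] <- switch(spec[[cn]],
                           chr = as.character(tb[[cn]]),
                           date = as_date(tb[[cn]]),
                           num = as.numeric(tb[[cn]]))
      }
      extra <- setdiff(names(tb), names(spec))
      tb <- tb[, c(names(spec), extra), drop = FALSE]
    }
    rownames(tb) <- NULL
    out[[nm]] <- tb
  }
  ds <- structure(out, class = "claims_dataset",
                  rejects = empty_rejects())
  if (validate) ds <- validate_claims(ds) else ds
}

empty_rejects <- function() {
  data.frame(table = character(0), row = integer(0), reason = character(0),
             stringsAsFactors = FALSE)
}

# Move invariant-violating rows out of the data into the rejects report.
validate_claims <- function(ds) {
  rejects <- list()
  flag_rows <- function(tbl_name, bad, reason) {
    idx <- which(bad)
    if (length(idx) > 0L) {
      rejects[[length(rejects) + 1L]] <<-
        data.frame(table = tbl_name, row = idx, reason = reason,
                   stringsAsFactors = FALSE)
    }
    bad & !is.na(bad)
  }
  drop <- function(tbl, bad) tbl[!(bad %in% TRUE), , drop = FALSE]

  p <- ds$persons
  bad <- flag_rows("persons", is.na(p$birth_date) | !nzchar(p$person_id),
                   "missing person_id or unparseable birth_date")
  bad <- bad | flag_rows("persons", duplicated(p$person_id), "duplicate person_id")
  ds$persons <- drop(p, bad)

  e <- ds$enrollment
  bad <- flag_rows("enrollment", is.na(e$start_date) | is.na(e$end_date),
                   "unparseable date")
  bad <- bad | flag_rows("enrollment", !is.na(e$start_date) & !is.na(e$end_date) &
                           e$end_date < e$start_date, "end_date before start_date")
  ds$enrollment <- drop(e, bad)

  ip <- ds$inpatient
  bad <- flag_rows("inpatient", is.na(ip$admission_date) | is.na(ip$discharge_date),
                   "unparseable date")
  bad <- bad | flag_rows("inpatient",
                         !is.na(ip$admission_date) & !is.na(ip$discharge_date) &
                           ip$discharge_date < ip$admission_date,
                         "discharge before admission")
  ds$inpatient <- drop(ip, bad)

  ov <- ds$outpatient
  bad <- flag_rows("outpatient", is.na(ov$visit_date), "unparseable date")
  bad <- bad | flag_rows("outpatient", !ov$setting %in% OUTPATIENT_SETTINGS,
                         "setting outside vocabulary")
  ds$outpatient <- drop(ov, bad)

  rx <- ds$prescriptions
  bad <- flag_rows("prescriptions", is.na(rx$fill_date), "unparseable date")
  bad <- bad | flag_rows("prescriptions", !rx$drug_class %in% DRUG_CLASSES,
                         "drug_class outside vocabulary")
  ds$prescriptions <- drop(rx, bad)

  pc <- ds$procedures
  bad <- flag_rows("procedures", is.na(pc$service_date), "unparseable date")
  bad <- bad | flag_rows("procedures", !nzchar(gsub("[[:space:]]", "", pc$procedure_code)),
                         "empty procedure_code")
  ds$procedures <- drop(pc, bad)

  xf <- ds$exclusion_flags
  if (nrow(xf) > 0L) {
    bad <- flag_rows("exclusion_flags", is.na(xf$start_date) | is.na(xf$end_date),
                     "unparseable date")
    bad <- bad | flag_rows("exclusion_flags", !xf$flag %in% EXCLUSION_FLAGS,
                           "flag outside vocabulary")
    ds$exclusion_flags <- drop(xf, bad)
  }

  attr(ds, "rejects") <- if (length(rejects) > 0L) {
    do.call(rbind, rejects)
  } else {
    empty_rejects()
  }
  ds
}

#' Read a claims dataset from a directory of CSV files
#'
#' Expects `persons.csv`, `enrollment.csv`, `inpatient.csv`, `outpatient.csv`,
#' `prescriptions.csv` and `procedures.csv` (plus optional
#' `exclusion_flags.csv`), comma-separated UTF-8 with one header row and
#' ISO-8601 dates. Multi-valued diagnosis cells are semicolon-delimited.
#' Rows failing type or invariant checks land in the rejects report
#' (`claims_rejects()`).
#'
#' @param dir_path Directory containing the CSV files.
#' @param strict Error if any row is rejected (default `FALSE`).
#' @return A `claims_dataset`.
#' @export
read_claims <- function(dir_path, strict = FALSE) {
  paths <- file.path(dir_path, CLAIMS_FILES)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing claims file(s): ",
         paste(CLAIMS_FILES[missing], collapse = ", "), " in ", dir_path,
         call. = FALSE)
  }
  read_one <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = character(0))
  }
  tables <- lapply(paths, read_one)
  names(tables) <- names(CLAIMS_FILES)
  xf_path <- file.path(dir_path, "exclusion_flags.csv")
  if (file.exists(xf_path)) tables$exclusion_flags <- read_one(xf_path)
  ds <- do.call(claims_dataset, tables)
  rej <- claims_rejects(ds)
  if (strict && nrow(rej) > 0L) {
    stop("strict mode: ", nrow(rej), " row(s) rejected during validation; ",
         "first: ", rej$table[1], " row ", rej$row[1], " (", rej$reason[1], ")",
         call. = FALSE)
  }
  ds
}

#' Write a claims dataset to a directory of CSV files
#'
#' Inverse of [read_claims()]: emits the standard file set with ISO-8601
#' dates, suitable for bit-exact round-tripping.
#'
#' @param dataset A `claims_dataset`.
#' @param dir_path Output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_claims <- function(dataset, dir_path) {
  stopifnot(inherits(dataset, "claims_dataset"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(CLAIMS_FILES)) {
    utils::write.csv(dataset[[nm]], file.path(dir_path, CLAIMS_FILES[[nm]]),
                     row.names = FALSE)
  }
  if (nrow(dataset$exclusion_flags) > 0L) {
    utils::write.csv(dataset$exclusion_flags,
                     file.path(dir_path, "exclusion_flags.csv"),
                     row.names = FALSE)
  }
  invisible(dir_path)
}

#' Rejected rows from claims validation
#'
#' @param dataset A `claims_dataset`.
#' @return Data frame with columns `table`, `row` (1-based row in the source
#'   table) and `reason`.
#' @export
claims_rejects <- function(dataset) attr(dataset, "rejects") %||% empty_rejects()

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  for (nm in names(CLAIMS_SCHEMA)) {
    cat(sprintf("  %-16s %6d rows\n", nm, nrow(x[[nm]])))
  }
  nr <- nrow(claims_rejects(x))
  if (nr > 0L) cat("  rejected rows:", nr, "\n")
  invisible(x)
}

#' Merge enrollment spells, tolerating short coverage lapses
#'
#' Overlapping or abutting spells are merged; spells separated by a gap of at
#' most `max_gap_days` are also merged, the gap being considered covered. Gap
#' length between consecutive spells is `next start - previous end - 1` days
#' (a spell ending March 31 and one starting April 1 have zero gap). Handles
#' multiple persons; output is sorted and disjoint within person.
#'
#' @param spells Data frame with `person_id`, `start_date`, `end_date`.
#' @param max_gap_days Longest lapse still counted as continuous coverage
#'   (default 7).
#' @return Data frame of normalized spells.
#' @export
normalize_enrollment <- function(spells, max_gap_days = 7L) {
  spells <- as.data.frame(spells, stringsAsFactors = FALSE)
  if (nrow(spells) == 0L) {
    return(empty_tbl(CLAIMS_SCHEMA$enrollment))
  }
  spells$start_date <- as_date(spells$start_date)
  spells$end_date <- as_date(spells$end_date)
  spells <- spells[order(spells$person_id, spells$start_date, spells$end_date), ,
                   drop = FALSE]
  out <- lapply(split(spells, spells$person_id), function(s) {
    starts <- s$start_date
    ends <- s$end_date
    ks <- starts[1]
    ke <- ends[1]
    res_s <- res_e <- list()
    j <- 0L
    for (i in seq_len(nrow(s))[-1]) {
      gap <- as.integer(starts[i] - ke) - 1L
      if (gap <= max_gap_days) {
        if (ends[i] > ke) ke <- ends[i]
      } else {
        j <- j + 1L
        res_s[[j]] <- ks; res_e[[j]] <- ke
        ks <- starts[i]; ke <- ends[i]
      }
    }
    j <- j + 1L
    res_s[[j]] <- ks; res_e[[j]] <- ke
    data.frame(person_id = s$person_id[1],
               start_date = do.call(c, res_s),
               end_date = do.call(c, res_e),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Is every day of [from, to] covered by (normalized) spells of one person?
covers_interval <- function(norm_spells, from, to) {
  any(norm_spells$start_date <= from & norm_spells$end_date >= to)
}
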
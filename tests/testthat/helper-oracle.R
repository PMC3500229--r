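# Brute-force oracle for first-encounter identification and confirmation,
# written independently of the engine: plain loops over raw claim rows, its
# own code matching, no shared helpers. Used to cross-check the engine on
# random small persons.

oracle_norm <- function(x) toupper(sub(".", "", gsub(" ", "", x), fixed = TRUE))
oracle_is_dm <- function(code) {
  nc <- oracle_norm(code)
  nzchar(nc) & substr(nc, 1, 3) == "250"
}
oracle_is_dm_primary <- function(code) {
  nc <- oracle_norm(code)
  nc == "250" | substr(nc, 1, 4) %in% c("2500", "2501", "2502", "2503", "2509")
}
oracle_cell_dm <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) return(FALSE)
  any(oracle_is_dm(strsplit(cell, ";", fixed = TRUE)[[1]]))
}
oracle_cell_match <- function(cell, pred) {
  if (is.na(cell) || !nzchar(cell)) return(FALSE)
  any(pred(strsplit(cell, ";", fixed = TRUE)[[1]]))
}
oracle_is_pcos <- function(code) startsWith(oracle_norm(code), "2564")
oracle_is_menses <- function(code) {
  nc <- oracle_norm(code)
  startsWith(nc, "6260") | startsWith(nc, "6261") | startsWith(nc, "6264")
}
DM_CLASSES <- c("insulin", "insulin_adjunct", "oral_hypoglycemic")
MGMT_CODES <- c("83036", "82947", "82950", "82951")

oracle_pcos_dates <- function(ov, ip) {
  out <- as.Date(character(0))
  for (i in seq_len(nrow(ov))) {
    if (oracle_is_pcos(ov$primary_dx[i]) ||
        oracle_cell_match(ov$secondary_dx[i], oracle_is_pcos)) {
      out <- c(out, ov$visit_date[i])
    }
  }
  for (i in seq_len(nrow(ip))) {
    if (oracle_is_pcos(ip$primary_dx[i]) ||
        oracle_cell_match(ip$secondary_dx[i], oracle_is_pcos) ||
        oracle_cell_match(ip$admission_dx[i], oracle_is_pcos)) {
      out <- c(out, ip$admission_date[i])
    }
  }
  out
}

# Enumerate every candidate encounter of one person, then report the earliest
# (ties: inpatient-primary > inpatient-secondary > outpatient > prescription).
oracle_first_encounter <- function(ds, pid, fstart, fend) {
  ov <- ds$outpatient[ds$outpatient$person_id == pid, , drop = FALSE]
  ip <- ds$inpatient[ds$inpatient$person_id == pid, , drop = FALSE]
  rx <- ds$prescriptions[ds$prescriptions$person_id == pid, , drop = FALSE]
  pcos <- oracle_pcos_dates(ov, ip)

  cand_type <- character(0)
  cand_tx <- cand_claim <- as.Date(character(0))

  stay_tx <- function(adm) {
    for (j in seq_len(nrow(ov))) {
      if (ov$setting[j] %in% c("outpatient", "emergency") &&
          ov$visit_date[j] == adm - 1 &&
          (oracle_is_dm(ov$primary_dx[j]) || oracle_cell_dm(ov$secondary_dx[j]))) {
        return(adm - 1)
      }
    }
    adm
  }

  for (i in seq_len(nrow(ip))) {
    if (oracle_is_dm_primary(ip$primary_dx[i])) {
      cand_type <- c(cand_type, "inpatient_primary")
      cand_tx <- c(cand_tx, stay_tx(ip$admission_date[i]))
      cand_claim <- c(cand_claim, ip$admission_date[i])
    } else if (oracle_cell_dm(ip$secondary_dx[i]) ||
               oracle_cell_dm(ip$admission_dx[i])) {
      cand_type <- c(cand_type, "inpatient_secondary")
      cand_tx <- c(cand_tx, stay_tx(ip$admission_date[i]))
      cand_claim <- c(cand_claim, ip$admission_date[i])
    }
  }
  for (j in seq_len(nrow(ov))) {
    if (ov$setting[j] == "physician_inpatient" && oracle_is_dm(ov$primary_dx[j])) {
      hosts <- which(ip$admission_date - 1 <= ov$visit_date[j] &
                       ov$visit_date[j] <= ip$discharge_date + 1)
      if (length(hosts) > 0) {
        h <- hosts[which.min(ip$admission_date[hosts])]
        cand_type <- c(cand_type, "inpatient_secondary")
        cand_tx <- c(cand_tx, stay_tx(ip$admission_date[h]))
        cand_claim <- c(cand_claim, ip$admission_date[h])
      }
    }
    if (ov$setting[j] %in% c("outpatient", "emergency") &&
        oracle_is_dm(ov$primary_dx[j])) {
      in_stay <- any(ip$admission_date - 1 <= ov$visit_date[j] &
                       ov$visit_date[j] <= ip$discharge_date + 1)
      if (!in_stay) {
        cand_type <- c(cand_type, "outpatient")
        cand_tx <- c(cand_tx, ov$visit_date[j])
        cand_claim <- c(cand_claim, ov$visit_date[j])
      }
    }
  }
  for (k in seq_len(nrow(rx))) {
    if (rx$drug_class[k] %in% DM_CLASSES) {
      t <- rx$fill_date[k]
      if (!any(pcos >= t - 120 & pcos <= t + 120)) {
        cand_type <- c(cand_type, "prescription")
        cand_tx <- c(cand_tx, t)
        cand_claim <- c(cand_claim, t)
      }
    }
  }

  keep <- cand_claim >= fstart & cand_claim <= fend
  if (!any(keep)) return(NULL)
  cand_type <- cand_type[keep]; cand_tx <- cand_tx[keep]
  rank <- match(cand_type, c("inpatient_primary", "inpatient_secondary",
                             "outpatient", "prescription"))
  best <- order(cand_tx, rank)[1]
  list(encounter_type = cand_type[best], t_x = cand_tx[best])
}

# Full oracle verdict (met / not met) for one member under one variant.
oracle_verdict <- function(ds, pid, fstart, fend, variant) {
  first <- oracle_first_encounter(ds, pid, fstart, fend)
  if (is.null(first)) return(list(met = FALSE, encounter = NULL))
  ov <- ds$outpatient[ds$outpatient$person_id == pid, , drop = FALSE]
  ip <- ds$inpatient[ds$inpatient$person_id == pid, , drop = FALSE]
  rx <- ds$prescriptions[ds$prescriptions$person_id == pid, , drop = FALSE]
  pr <- ds$procedures[ds$procedures$person_id == pid, , drop = FALSE]
  t <- first$t_x
  typ <- first$encounter_type

  if (typ != "inpatient_primary") {
    pcos <- oracle_pcos_dates(ov, ip)
    if (any(pcos >= t - 120 & pcos <= t + 120)) {
      return(list(met = FALSE, encounter = first, excluded = TRUE))
    }
  }

  in_win <- function(dates) dates > t & dates <= fend
  fills <- rx$fill_date[rx$drug_class %in% DM_CLASSES]
  op_dx <- ov$visit_date[oracle_is_dm(ov$primary_dx)]
  ip_dx <- ip$admission_date[
    oracle_is_dm(ip$primary_dx) |
      vapply(ip$secondary_dx, oracle_cell_dm, logical(1)) |
      vapply(ip$admission_dx, oracle_cell_dm, logical(1))]
  mgmt <- pr$service_date[oracle_norm(pr$procedure_code) %in% MGMT_CODES]
  hba1c <- pr$service_date[oracle_norm(pr$procedure_code) == "83036"]
  menses <- as.Date(character(0))
  for (j in seq_len(nrow(ov))) {
    if (oracle_is_menses(ov$primary_dx[j]) ||
        oracle_cell_match(ov$secondary_dx[j], oracle_is_menses)) {
      menses <- c(menses, ov$visit_date[j])
    }
  }
  for (i in seq_len(nrow(ip))) {
    if (oracle_is_menses(ip$primary_dx[i]) ||
        oracle_cell_match(ip$secondary_dx[i], oracle_is_menses) ||
        oracle_cell_match(ip$admission_dx[i], oracle_is_menses)) {
      menses <- c(menses, ip$admission_date[i])
    }
  }

  met <- if (typ == "inpatient_primary") {
    TRUE
  } else if (typ == "inpatient_secondary") {
    variant == "secondary" || any(in_win(fills)) || any(in_win(op_dx)) ||
      any(in_win(ip_dx))
  } else if (typ == "outpatient") {
    any(in_win(fills)) || any(in_win(ip_dx)) ||
      (variant == "secondary" && any(in_win(hba1c)))
  } else {
    any(in_win(op_dx)) || any(in_win(ip_dx)) ||
      (any(in_win(fills)) && any(in_win(mgmt)) && !any(in_win(menses)))
  }
  list(met = met, encounter = first, excluded = FALSE)
}

# Random small person for oracle cross-checks: claims drawn from a code pool
# rich in edge cases (non-listed 250.4x family, PCOS, menses, V-codes).
random_person_tables <- function(pid, fstart, fend) {
  pool_dx <- c("250.00", "250.01", "250.11", "250.41", "250.9", "250",
               "V70.0", "256.4", "626.0", "786.2")
  pool_proc <- c("83036", "82947", "82950", "90658", "99213")
  span <- as.integer(fend - fstart)
  rnd_date <- function(n) fstart + sample(-60:(span + 60), n, replace = TRUE)
  n_ov <- rpois(1, 3); n_ip <- rpois(1, 0.7); n_rx <- rpois(1, 2)
  n_pr <- rpois(1, 1.5)
  ov <- if (n_ov > 0) {
    data.frame(person_id = pid, visit_date = rnd_date(n_ov),
               primary_dx = sample(pool_dx, n_ov, replace = TRUE),
               secondary_dx = ifelse(runif(n_ov) < 0.3,
                                     sample(pool_dx, n_ov, replace = TRUE), ""),
               setting = sample(c("outpatient", "emergency",
                                  "physician_inpatient"), n_ov,
                                replace = TRUE, prob = c(0.6, 0.2, 0.2)),
               stringsAsFactors = FALSE)
  }
  ip <- if (n_ip > 0) {
    adm <- rnd_date(n_ip)
    data.frame(person_id = pid, admission_date = adm,
               discharge_date = adm + sample(0:10, n_ip, replace = TRUE),
               primary_dx = sample(pool_dx, n_ip, replace = TRUE),
               secondary_dx = ifelse(runif(n_ip) < 0.5,
                                     sample(pool_dx, n_ip, replace = TRUE), ""),
               admission_dx = ifelse(runif(n_ip) < 0.3,
                                     sample(pool_dx, n_ip, replace = TRUE), ""),
               stringsAsFactors = FALSE)
  }
  rx <- if (n_rx > 0) {
    data.frame(person_id = pid, fill_date = rnd_date(n_rx),
               drug_class = sample(c("insulin", "oral_hypoglycemic",
                                     "insulin_adjunct", "other"), n_rx,
                                   replace = TRUE, prob = c(0.3, 0.4, 0.1, 0.2)),
               drug_name = "x", stringsAsFactors = FALSE)
  }
  pr <- if (n_pr > 0) {
    data.frame(person_id = pid, service_date = rnd_date(n_pr),
               procedure_code = sample(pool_proc, n_pr, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  list(outpatient = ov, inpatient = ip, prescriptions = rx, procedures = pr)
}
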
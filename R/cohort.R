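#' EHR cohort container
#'
#' An `hf_cohort` bundles the seven flat tables the pipeline consumes:
#' a patient roster plus child tables of diagnoses, free-text imaging
#' reports, structured cath-lab LVEF entries (CART-style), medication
#' orders, admissions, and specialty encounters. All child tables are
#' keyed by `patient_id` and must reference roster patients.
#'
#' @param roster tibble with columns `patient_id`, `facility_id`,
#'   `provider_id`, `network_id` (all non-empty strings; `patient_id`
#'   unique).
#' @param diagnoses tibble: `patient_id`, `code`, `code_system`
#'   (`"ICD9"`/`"ICD10"`), `record_date` (Date), `origin`
#'   (`"encounter"`/`"problem_list"`), `active` (logical; meaningful for
#'   problem-list rows only).
#' @param imaging tibble: `report_id`, `patient_id`, `report_date`
#'   (Date), `source_system` (`"echo"`/`"clinical_note"`/`"radiology"`),
#'   `modality_hint` (`"TTE"`/`"TEE"`/`"nuclear"`/`"other"` or `NA`),
#'   `text` (free text, may be empty).
#' @param cart tibble: `patient_id`, `record_date` (Date), `lvef`
#'   (percent in (0, 100]), `source_modality` (`"TTE"`/`"TEE"`/`"MRI"`/
#'   `"CT"`/`"ventriculography"`/`"nuclear"`). One LVEF per record.
#' @param medications tibble: `patient_id`, `drug_name`, `dose`
#'   (numeric, `NA` if unparseable), `dose_unit`, `start_date`,
#'   `end_date` (Date, `NA` = still active).
#' @param admissions tibble: `patient_id`, `admit_date` (Date),
#'   `primary_dx_is_hf` (logical).
#' @param encounters tibble: `patient_id`, `encounter_date` (Date),
#'   `specialty`.
#' @return An object of class `hf_cohort` (a named list of tibbles).
#' @export
hf_cohort <- function(roster,
                      diagnoses = empty_table("diagnoses"),
                      imaging = empty_table("imaging"),
                      cart = empty_table("cart"),
                      medications = empty_table("medications"),
                      admissions = empty_table("admissions"),
                      encounters = empty_table("encounters")) {
  cohort <- structure(
    list(roster = tibble::as_tibble(roster),
         diagnoses = tibble::as_tibble(diagnoses),
         imaging = tibble::as_tibble(imaging),
         cart = tibble::as_tibble(cart),
         medications = tibble::as_tibble(medications),
         admissions = tibble::as_tibble(admissions),
         encounters = tibble::as_tibble(encounters)),
    class = "hf_cohort")
  validate_cohort(cohort)
}

cohort_schemas <- list(
  roster      = c(patient_id = "c", facility_id = "c", provider_id = "c",
                  network_id = "c"),
  diagnoses   = c(patient_id = "c", code = "c", code_system = "c",
                  record_date = "D", origin = "c", active = "l"),
  imaging     = c(report_id = "c", patient_id = "c", report_date = "D",
                  source_system = "c", modality_hint = "c", text = "c"),
  cart        = c(patient_id = "c", record_date = "D", lvef = "d",
                  source_modality = "c"),
  medications = c(patient_id = "c", drug_name = "c", dose = "d",
                  dose_unit = "c", start_date = "D", end_date = "D"),
  admissions  = c(patient_id = "c", admit_date = "D",
                  primary_dx_is_hf = "l"),
  encounters  = c(patient_id = "c", encounter_date = "D", specialty = "c")
)

proto_col <- function(code) {
  switch(code,
         c = character(), d = double(), l = logical(),
         D = as.Date(character()))
}

empty_table <- function(name) {
  schema <- cohort_schemas[[name]]
  tibble::as_tibble(lapply(setNames(as.list(schema), names(schema)), proto_col))
}

check_levels <- function(x, allowed, table, col, na_ok = FALSE) {
  vals <- unique(x)
  if (na_ok) vals <- vals[!is.na(vals)]
  bad <- vals[vals %notin% allowed]
  if (length(bad) > 0) {
    abort(sprintf("%s$%s contains invalid value(s): %s (allowed: %s)",
                  table, col, paste(bad, collapse = ", "),
                  paste(allowed, collapse = ", ")))
  }
}

validate_cohort <- function(cohort) {
  for (name in names(cohort_schemas)) {
    schema <- cohort_schemas[[name]]
    tbl <- cohort[[name]]
    missing <- setdiff(names(schema), names(tbl))
    if (length(missing) > 0) {
      abort(sprintf("table '%s' is missing column(s): %s",
                    name, paste(missing, collapse = ", ")))
    }
    tbl <- tbl[names(schema)]
    for (col in names(schema)) {
      tbl[[col]] <- switch(schema[[col]],
                           c = as.character(tbl[[col]]),
                           d = as.double(tbl[[col]]),
                           l = as.logical(tbl[[col]]),
                           D = as_iso_date(tbl[[col]],
                                           paste0(name, "$", col)))
    }
    cohort[[name]] <- tbl
  }
  roster <- cohort$roster
  if (anyDuplicated(roster$patient_id) > 0) {
    abort("roster patient_id values must be unique")
  }
  id_cols <- c("patient_id", "facility_id", "provider_id", "network_id")
  for (col in id_cols) {
    if (any(is.na(roster[[col]]) | roster[[col]] == "")) {
      abort(sprintf("roster$%s must be non-empty", col))
    }
  }
  for (name in setdiff(names(cohort_schemas), "roster")) {
    unknown <- setdiff(cohort[[name]]$patient_id, roster$patient_id)
    if (length(unknown) > 0) {
      abort(sprintf(
        "referential integrity: %s rows reference patient_id(s) not in roster: %s",
        name, paste(unique(unknown), collapse = ", ")))
    }
  }
  check_levels(cohort$diagnoses$code_system, c("ICD9", "ICD10"),
               "diagnoses", "code_system")
  check_levels(cohort$diagnoses$origin, c("encounter", "problem_list"),
               "diagnoses", "origin")
  if (any(is.na(cohort$diagnoses$code) | cohort$diagnoses$code == "")) {
    abort("diagnoses$code must be non-empty")
  }
  check_levels(cohort$imaging$source_system,
               c("echo", "clinical_note", "radiology"),
               "imaging", "source_system")
  check_levels(cohort$imaging$modality_hint,
               c("TTE", "TEE", "nuclear", "other"),
               "imaging", "modality_hint", na_ok = TRUE)
  check_levels(cohort$cart$source_modality,
               c("TTE", "TEE", "MRI", "CT", "ventriculography", "nuclear"),
               "cart", "source_modality")
  if (any(cohort$cart$lvef <= 0 | cohort$cart$lvef > 100, na.rm = TRUE) ||
      anyNA(cohort$cart$lvef)) {
    abort("cart$lvef must be numeric in (0, 100]")
  }
  meds <- cohort$medications
  bad <- !is.na(meds$end_date) & meds$end_date < meds$start_date
  if (any(bad, na.rm = TRUE)) {
    abort("medications: end_date precedes start_date")
  }
  # canonical row order so that write/read round-trips are identities
  for (name in names(cohort_schemas)) {
    cohort[[name]] <- sort_table(cohort[[name]])
  }
  cohort
}

#' @export
print.hf_cohort <- function(x, ...) {
  cat("<hf_cohort>", nrow(x$roster), "patients\n")
  for (name in setdiff(names(cohort_schemas), "roster")) {
    cat(sprintf("  %-12s %d rows\n", name, nrow(x[[name]])))
  }
  invisible(x)
}

sort_table <- function(tbl) {
  if (nrow(tbl) == 0) return(tbl)
  dplyr::arrange(tbl, dplyr::across(dplyr::everything()))
}

cohort_file_names <- c(
  roster = "roster.csv", diagnoses = "diagnoses.csv",
  imaging = "imaging_reports.jsonl", cart = "cart.csv",
  medications = "medications.csv", admissions = "admissions.csv",
  encounters = "encounters.csv")

#' Write a cohort to a directory of flat files
#'
#' One RFC-4180 CSV per structured table plus JSON-lines for imaging
#' reports (free text with embedded newlines survives). Output is
#' deterministic: fixed column order, rows sorted by all columns, dates
#' as ISO-8601. `read_cohort(write_cohort(x))` returns `x`.
#'
#' @param cohort an [hf_cohort()].
#' @param dir output directory, created if absent.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory '%s'", dir))
  paths <- file.path(dir, cohort_file_names)
  names(paths) <- names(cohort_file_names)
  for (name in names(cohort_file_names)) {
    tbl <- sort_table(cohort[[name]][names(cohort_schemas[[name]])])
    if (name == "imaging") {
      lines <- vapply(seq_len(nrow(tbl)), function(i) {
        row <- as.list(tbl[i, ])
        row$report_date <- format(row$report_date, "%Y-%m-%d")
        jsonlite::toJSON(row, auto_unbox = TRUE, null = "null", na = "null")
      }, character(1))
      writeLines(lines, paths[[name]], useBytes = TRUE)
    } else {
      readr::write_csv(tbl, paths[[name]], na = "")
    }
  }
  invisible(paths)
}

#' Read a cohort from a directory of flat files
#'
#' Inverse of [write_cohort()]. Dates must be ISO-8601 (`YYYY-MM-DD`);
#' any other form is a fatal error naming the offending rows. Every
#' child-table `patient_id` must exist in the roster.
#'
#' @param dir directory containing the cohort files.
#' @return An [hf_cohort()].
#' @export
read_cohort <- function(dir) {
  paths <- file.path(dir, cohort_file_names)
  names(paths) <- names(cohort_file_names)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("missing cohort file(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tables <- list()
  for (name in names(cohort_file_names)) {
    schema <- cohort_schemas[[name]]
    if (name == "imaging") {
      lines <- readLines(paths[[name]], warn = FALSE)
      if (length(lines) == 0) {
        tables[[name]] <- empty_table("imaging")
      } else {
        rows <- lapply(lines, function(l) {
          x <- jsonlite::fromJSON(l)
          x[vapply(x, is.null, logical(1))] <- NA_character_
          tibble::as_tibble(x)
        })
        tbl <- dplyr::bind_rows(rows)
        tbl$report_date <- as_iso_date(tbl$report_date, "imaging$report_date")
        tables[[name]] <- tbl
      }
    } else {
      col_types <- paste(vapply(schema, function(code) {
        switch(code, c = "c", d = "d", l = "l", D = "c")
      }, character(1)), collapse = "")
      tbl <- readr::read_csv(paths[[name]], col_types = col_types,
                             na = "", progress = FALSE)
      for (col in names(schema)[schema == "D"]) {
        tbl[[col]] <- as_iso_date(tbl[[col]], paste0(name, "$", col))
      }
      tables[[name]] <- tbl
    }
  }
  hf_cohort(roster = tables$roster, diagnoses = tables$diagnoses,
            imaging = tables$imaging, cart = tables$cart,
            medications = tables$medications, admissions = tables$admissions,
            encounters = tables$encounters)
}
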
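#' Does a patient have documented heart failure?
#'
#' Inclusion requires a documented diagnosis: either an encounter
#' diagnosis matching the HF code set on or before the reference date,
#' or an active HF entry in the problem list. Patients with LVEF
#' evidence but no documented diagnosis are excluded — chart review of
#' such patients found only a minority with true clinical HF.
#'
#' @param diagnoses diagnosis rows for one patient.
#' @param cfg a [classification_config()] (supplies `hf_code_prefixes`
#'   and `as_of_date`).
#' @return `TRUE` or `FALSE`.
#' @export
has_documented_hf <- function(diagnoses, cfg = classification_config()) {
  if (nrow(diagnoses) == 0) return(FALSE)
  is_hf <- code_matches(diagnoses$code, cfg$hf_code_prefixes)
  enc <- diagnoses$origin == "encounter" & is_hf &
    diagnoses$record_date <= cfg$as_of_date
  prob <- diagnoses$origin == "problem_list" & is_hf &
    !is.na(diagnoses$active) & diagnoses$active
  any(enc) || any(prob)
}

code_matches <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) {
    out <- out | startsWith(codes, p)
  }
  out
}

#' Classify an effective LVEF into an HF phenotype
#'
#' `HFrEF` for LVEF at or below `hfref_max` (default 40), `HFpEF` at or
#' above `hfmref_max + 1` (default 50), `HFmrEF` for the open interval
#' between them — non-integer averaged values fall in the interval rule
#' (40.5 is HFmrEF).
#'
#' @param effective_lvef LVEF percent in (0, 100].
#' @param cfg a [classification_config()].
#' @return `"HFrEF"`, `"HFmrEF"` or `"HFpEF"`.
#' @export
classify_lvef <- function(effective_lvef, cfg = classification_config()) {
  stopifnot(length(effective_lvef) == 1, !is.na(effective_lvef),
            effective_lvef > 0, effective_lvef <= 100)
  if (effective_lvef <= cfg$hfref_max) return("HFrEF")
  if (effective_lvef < cfg$hfmref_max + 1) return("HFmrEF")
  "HFpEF"
}

# legacy ICD-only fallback when no LVEF exists: systolic-HF codes map to
# HFrEF, diastolic to HFpEF, anything else to unspecified. Codes naming
# both (combined systolic+diastolic) count as systolic.
icd_fallback_phenotype <- function(diagnoses, cfg) {
  hf <- diagnoses[code_matches(diagnoses$code, cfg$hf_code_prefixes), ,
                  drop = FALSE]
  if (any(code_matches(hf$code, cfg$icd_fallback_map$HFrEF))) return("HFrEF")
  if (any(code_matches(hf$code, cfg$icd_fallback_map$HFpEF))) return("HFpEF")
  "unspecified"
}

#' Phenotype one patient
#'
#' Both algorithm versions first require documented HF. Version `v2`
#' applies the quality-aware selection cascade and maps the effective
#' LVEF through [classify_lvef()]; any unspecified verdict stays
#' unspecified. Version `v1` takes the lowest LVEF from any source in
#' the lookback window with only two classes (at or below `hfref_max`
#' is HFrEF, above it HFpEF) and falls back to ICD codes alone when no
#' LVEF exists.
#'
#' @param evidence evidence rows for the patient ([build_evidence()]).
#' @param diagnoses diagnosis rows for the patient.
#' @param cfg a [classification_config()].
#' @param version `"v1"` or `"v2"`.
#' @param patient_id used when both inputs are empty.
#' @return A one-row tibble: `patient_id`, `algorithm_version`,
#'   `included`, `phenotype` (`NA` when not included), `effective_lvef`,
#'   `rule_fired`, `verdict`.
#' @export
phenotype_patient <- function(evidence, diagnoses,
                              cfg = classification_config(),
                              version = c("v2", "v1"),
                              patient_id = NULL) {
  version <- match.arg(version)
  pid <- patient_id %||%
    c(evidence$patient_id, diagnoses$patient_id, NA_character_)[1]
  if (!has_documented_hf(diagnoses, cfg)) {
    return(tibble::tibble(patient_id = pid, algorithm_version = version,
                          included = FALSE, phenotype = NA_character_,
                          effective_lvef = NA_real_,
                          rule_fired = "no_documented_hf",
                          verdict = NA_character_))
  }
  sel <- if (version == "v2") {
    select_effective_lvef(evidence, cfg)
  } else {
    select_effective_lvef_v1(evidence, cfg)
  }
  phenotype <- if (sel$verdict == "value") {
    if (version == "v2") {
      classify_lvef(sel$effective_lvef, cfg)
    } else if (sel$effective_lvef <= cfg$hfref_max) "HFrEF" else "HFpEF"
  } else if (version == "v1" && sel$verdict == "unspecified_no_data") {
    icd_fallback_phenotype(diagnoses, cfg)
  } else {
    "unspecified"
  }
  rule <- sel$rule_fired
  if (version == "v1" && sel$verdict == "unspecified_no_data" &&
      phenotype != "unspecified") {
    rule <- "icd_only_fallback"
  }
  tibble::tibble(patient_id = pid, algorithm_version = version,
                 included = TRUE, phenotype = phenotype,
                 effective_lvef = sel$effective_lvef,
                 rule_fired = rule, verdict = sel$verdict)
}

#' Phenotype every patient in a cohort
#'
#' @param cohort an [hf_cohort()].
#' @param cfg a [classification_config()].
#' @param version `"v1"` or `"v2"`.
#' @param evidence optional precomputed [build_evidence()] table (saves
#'   re-running extraction when phenotyping both versions).
#' @return A tibble with one row per roster patient, ordered by
#'   `patient_id`, with the columns of [phenotype_patient()].
#' @export
phenotype_cohort <- function(cohort, cfg = classification_config(),
                             version = c("v2", "v1"), evidence = NULL) {
  version <- match.arg(version)
  stopifnot(inherits(cohort, "hf_cohort"))
  if (is.null(evidence)) evidence <- build_evidence(cohort)
  ev_split <- split(evidence, evidence$patient_id)
  dx_split <- split(cohort$diagnoses, cohort$diagnoses$patient_id)
  ids <- sort(cohort$roster$patient_id)
  rows <- lapply(ids, function(pid) {
    ev <- ev_split[[pid]] %||% evidence[0, , drop = FALSE]
    dx <- dx_split[[pid]] %||% cohort$diagnoses[0, , drop = FALSE]
    phenotype_patient(ev, dx, cfg, version, patient_id = pid)
  })
  dplyr::bind_rows(rows)
}

#' Write a phenotype table as CSV
#'
#' @param phenotypes tibble from [phenotype_cohort()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(dplyr::arrange(phenotypes, .data$patient_id), path,
                   na = "")
  invisible(path)
}
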
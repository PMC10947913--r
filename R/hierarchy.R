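#' Quality tier for one LVEF source
#'
#' Implements the imaging-quality hierarchy. High quality: a single-value
#' echocardiogram extracted by the text pipeline, or a structured
#' cath-lab (CART-style) entry sourced from TTE, TEE, MRI or cardiac CT.
#' Medium quality: multi-value echo extractions, clinical-note
#' extractions, and cath-lab entries sourced from ventriculography
#' (which tends to overestimate LVEF). Excluded: all radiology-report
#' extractions and nuclear-sourced cath-lab entries, both documented as
#' too inaccurate to classify patients.
#'
#' @param provenance one of `"nlp_echo"`, `"nlp_note"`,
#'   `"nlp_radiology"`, `"cart"`.
#' @param modality for `cart`, one of `"TTE"`, `"TEE"`, `"MRI"`, `"CT"`,
#'   `"ventriculography"`, `"nuclear"`; for text provenances the
#'   modality hint is not used for tiering and may be `NA`.
#' @param n_values number of LVEF values carried by the item (>= 1).
#' @return `"high"`, `"medium"` or `"excluded"`. Unknown combinations
#'   are an error: the hierarchy fails closed rather than guessing a
#'   tier.
#' @export
assign_tier <- function(provenance, modality = NA_character_, n_values = 1) {
  stopifnot(length(provenance) == 1, n_values >= 1)
  if (provenance == "nlp_echo") {
    return(if (n_values == 1) "high" else "medium")
  }
  if (provenance == "nlp_note") return("medium")
  if (provenance == "nlp_radiology") return("excluded")
  if (provenance == "cart") {
    if (is.na(modality)) {
      abort("cart evidence requires a source modality; refusing to tier")
    }
    return(switch(modality,
                  TTE = , TEE = , MRI = , CT = "high",
                  ventriculography = "medium",
                  nuclear = "excluded",
                  abort(sprintf(
                    "no hierarchy tier defined for cart modality '%s'",
                    modality))))
  }
  abort(sprintf("unknown evidence provenance '%s'", provenance))
}

imaging_provenance <- c(echo = "nlp_echo", clinical_note = "nlp_note",
                        radiology = "nlp_radiology")

#' Build the per-patient LVEF evidence table
#'
#' Runs the text extractor over every imaging report, merges in the
#' structured cath-lab entries, drops non-cardiac mentions (gallbladder
#' etc.), and assigns each remaining item a quality tier. Excluded-tier
#' items are retained, marked, for audit; selection never uses them.
#'
#' @param cohort an [hf_cohort()].
#' @param patterns pattern set from [lvef_patterns()].
#' @return A tibble with one row per evidence item: `patient_id`,
#'   `event_date`, `provenance`, `modality`, `n_values`, `values` (list
#'   column), `tier`.
#' @export
build_evidence <- function(cohort, patterns = lvef_patterns()) {
  stopifnot(inherits(cohort, "hf_cohort"))
  imaging_rows <- list()
  img <- cohort$imaging
  for (i in seq_len(nrow(img))) {
    mention <- extract_lvef(img[i, ], patterns)
    if (is.null(mention) || mention$non_cardiac) next
    prov <- imaging_provenance[[img$source_system[i]]]
    imaging_rows[[length(imaging_rows) + 1]] <- tibble::tibble(
      patient_id = img$patient_id[i],
      event_date = img$report_date[i],
      provenance = prov,
      modality = img$modality_hint[i],
      n_values = length(mention$values),
      values = list(mention$values))
  }
  cart_tbl <- cohort$cart
  cart_rows <- if (nrow(cart_tbl) > 0) {
    tibble::tibble(
      patient_id = cart_tbl$patient_id,
      event_date = cart_tbl$record_date,
      provenance = "cart",
      modality = cart_tbl$source_modality,
      n_values = 1L,
      values = lapply(cart_tbl$lvef, identity))
  } else NULL
  evidence <- dplyr::bind_rows(c(imaging_rows, list(cart_rows)))
  if (nrow(evidence) == 0) {
    return(tibble::tibble(patient_id = character(),
                          event_date = as.Date(character()),
                          provenance = character(), modality = character(),
                          n_values = integer(), values = list(),
                          tier = character()))
  }
  evidence$tier <- vapply(seq_len(nrow(evidence)), function(i) {
    assign_tier(evidence$provenance[i], evidence$modality[i],
                evidence$n_values[i])
  }, character(1))
  dplyr::arrange(evidence, .data$patient_id, .data$event_date,
                 .data$provenance)
}

#' Write the evidence audit table as CSV
#'
#' @param evidence tibble from [build_evidence()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_evidence_audit <- function(evidence, path) {
  flat <- dplyr::mutate(evidence,
    values = vapply(.data$values, paste, character(1), collapse = ";"))
  readr::write_csv(flat, path, na = "")
  invisible(path)
}
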
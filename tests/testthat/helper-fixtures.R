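# shared fixture builders; everything is generated in code at test time

`%||%` <- function(x, y) if (is.null(x)) y else x

AS_OF <- as.Date("2022-07-01")
CFG <- classification_config(as_of_date = AS_OF)

# one evidence row in the shape build_evidence() produces
mk_item <- function(patient_id = "P1", days_ago = 100, values = 35,
                    tier = "high", provenance = "nlp_echo",
                    modality = "TTE") {
  tibble::tibble(patient_id = patient_id,
                 event_date = AS_OF - days_ago,
                 provenance = provenance, modality = modality,
                 n_values = length(values), values = list(values),
                 tier = tier)
}

mk_items <- function(...) dplyr::bind_rows(...)

no_evidence <- function() mk_item()[0, , drop = FALSE]

mk_roster <- function(ids, facility = "F1", provider = "D1",
                      network = "N1") {
  tibble::tibble(patient_id = ids, facility_id = facility,
                 provider_id = provider, network_id = network)
}

mk_dx <- function(patient_id = "P1", code = "I50.9",
                  origin = "encounter", active = NA, days_ago = 100,
                  code_system = "ICD10") {
  tibble::tibble(patient_id = patient_id, code = code,
                 code_system = code_system,
                 record_date = AS_OF - days_ago, origin = origin,
                 active = active)
}

no_dx <- function() mk_dx()[0, , drop = FALSE]

mk_med <- function(patient_id = "P1", drug = "metoprolol succinate",
                   dose = 200, start_days_ago = 200, end_days_ago = NA) {
  tibble::tibble(patient_id = patient_id, drug_name = drug, dose = dose,
                 dose_unit = "mg", start_date = AS_OF - start_days_ago,
                 end_date = if (is.na(end_days_ago)) as.Date(NA)
                            else AS_OF - end_days_ago)
}

no_meds <- function() mk_med()[0, , drop = FALSE]

mk_adm <- function(patient_id = "P1", days_ago, hf = TRUE) {
  tibble::tibble(patient_id = patient_id, admit_date = AS_OF - days_ago,
                 primary_dx_is_hf = hf)
}

no_adm <- function() mk_adm(days_ago = 1)[0, , drop = FALSE]

mk_enc <- function(patient_id = "P1", days_ago, specialty = "cardiology") {
  tibble::tibble(patient_id = patient_id,
                 encounter_date = AS_OF - days_ago, specialty = specialty)
}

no_enc <- function() mk_enc(days_ago = 1)[0, , drop = FALSE]

# random evidence set spanning both windows and all tiers, for the
# oracle-equivalence checks
random_evidence <- function(n_items) {
  combos <- list(
    list(provenance = "nlp_echo", modality = "TTE"),
    list(provenance = "nlp_echo", modality = "TEE"),
    list(provenance = "nlp_note", modality = NA_character_),
    list(provenance = "nlp_radiology", modality = "other"),
    list(provenance = "cart", modality = "TTE"),
    list(provenance = "cart", modality = "MRI"),
    list(provenance = "cart", modality = "ventriculography"),
    list(provenance = "cart", modality = "nuclear"))
  rows <- lapply(seq_len(n_items), function(i) {
    combo <- combos[[sample.int(length(combos), 1)]]
    n_vals <- if (combo$provenance == "cart") 1L else sample(1:3, 1)
    values <- sample(5:95, n_vals)
    tibble::tibble(
      patient_id = "PX",
      event_date = AS_OF - sample.int(1650, 1) + 1L,
      provenance = combo$provenance, modality = combo$modality,
      n_values = n_vals, values = list(values),
      tier = assign_tier(combo$provenance, combo$modality, n_vals))
  })
  dplyr::bind_rows(rows)
}
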
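#' Simulation parameters for synthetic EHR cohorts
#'
#' The generator emulates the documented failure modes of multi-source
#' LVEF capture: multi-value echo reports, clinical-note and radiology
#' text mentions, structured cath-lab entries with a clinician-entered
#' source modality, systematically inaccurate nuclear-study EFs,
#' gallbladder-EF contamination of radiology text, and imperfect ICD
#' coding. Every random draw flows from `seed`.
#'
#' @param n_patients cohort size.
#' @param seed integer seed.
#' @param as_of_date reference date all windows end at.
#' @param phenotype_prevalence probabilities over HFrEF/HFmrEF/HFpEF;
#'   must sum to 1.
#' @param true_lvef_bands per-phenotype integer LVEF band `(lo, hi)`;
#'   the defaults keep a 2-point guard away from the class boundaries so
#'   noise-free recovery is exact and boundary semantics are exercised
#'   by dedicated tests instead.
#' @param studies_min,studies_lambda studies per patient are
#'   `studies_min + Poisson(studies_lambda)`.
#' @param timeline_years studies are dated uniformly over this many
#'   years before `as_of_date` (the last 300 days when
#'   `recent_only = TRUE`).
#' @param recent_only if `TRUE` every study falls within the past year.
#' @param source_mix probabilities over `nlp_echo`, `nlp_note`,
#'   `nlp_radiology`, `cart`.
#' @param cart_modality_mix probabilities over the cath-lab source
#'   modalities.
#' @param p_multi_value_echo chance an echo report carries two LVEF
#'   values; the second differs by 1-15 points.
#' @param nuclear_bias,nuclear_sd additive Gaussian error applied to
#'   nuclear-sourced EFs (defaults -10 and 15, clipped to (5, 95)).
#' @param p_radiology_noncardiac chance a radiology report carries a
#'   gallbladder EF instead of a cardiac one.
#' @param p_icd_missing chance a patient has no HF diagnosis anywhere
#'   (excluded from the dashboard).
#' @param p_icd_false_positive chance of an extra non-HF decoy
#'   diagnosis code.
#' @param p_problem_list_active chance a coded patient also has an
#'   active problem-list HF entry.
#' @param p_gdmt,p_gdmt_target,p_high_risk_med,lambda_hf_admissions,
#'   p_cardiology_encounter medication/utilization generation rates for
#'   the KPI surface.
#' @return A list of class `hf_sim_params`.
#' @export
sim_params <- function(n_patients = 500,
                       seed = 20220701,
                       as_of_date = "2022-07-01",
                       phenotype_prevalence = c(HFrEF = 0.40,
                                                HFmrEF = 0.15,
                                                HFpEF = 0.45),
                       true_lvef_bands = list(HFrEF = c(15, 38),
                                              HFmrEF = c(43, 47),
                                              HFpEF = c(52, 70)),
                       studies_min = 1,
                       studies_lambda = 1.5,
                       timeline_years = 4,
                       recent_only = FALSE,
                       source_mix = c(nlp_echo = 0.45, nlp_note = 0.15,
                                      nlp_radiology = 0.20, cart = 0.20),
                       cart_modality_mix = c(TTE = 0.35, TEE = 0.05,
                                             MRI = 0.05, CT = 0.05,
                                             ventriculography = 0.15,
                                             nuclear = 0.35),
                       p_multi_value_echo = 0.20,
                       nuclear_bias = -10,
                       nuclear_sd = 15,
                       p_radiology_noncardiac = 0.15,
                       p_icd_missing = 0.10,
                       p_icd_false_positive = 0.05,
                       p_problem_list_active = 0.60,
                       p_gdmt = 0.50,
                       p_gdmt_target = 0.50,
                       p_high_risk_med = 0.10,
                       lambda_hf_admissions = 0.40,
                       p_cardiology_encounter = 0.50) {
  params <- list(n_patients = n_patients, seed = seed,
                 as_of_date = as_iso_date(as_of_date, "as_of_date"),
                 phenotype_prevalence = phenotype_prevalence,
                 true_lvef_bands = true_lvef_bands,
                 studies_min = studies_min,
                 studies_lambda = studies_lambda,
                 timeline_years = timeline_years,
                 recent_only = recent_only,
                 source_mix = source_mix,
                 cart_modality_mix = cart_modality_mix,
                 p_multi_value_echo = p_multi_value_echo,
                 nuclear_bias = nuclear_bias, nuclear_sd = nuclear_sd,
                 p_radiology_noncardiac = p_radiology_noncardiac,
                 p_icd_missing = p_icd_missing,
                 p_icd_false_positive = p_icd_false_positive,
                 p_problem_list_active = p_problem_list_active,
                 p_gdmt = p_gdmt, p_gdmt_target = p_gdmt_target,
                 p_high_risk_med = p_high_risk_med,
                 lambda_hf_admissions = lambda_hf_admissions,
                 p_cardiology_encounter = p_cardiology_encounter)
  validate_sim_params(structure(params, class = "hf_sim_params"))
}

validate_sim_params <- function(params) {
  probs <- c(params$p_multi_value_echo, params$p_radiology_noncardiac,
             params$p_icd_missing, params$p_icd_false_positive,
             params$p_problem_list_active, params$p_gdmt,
             params$p_gdmt_target, params$p_high_risk_med,
             params$p_cardiology_encounter, params$source_mix,
             params$cart_modality_mix)
  if (any(probs < 0 | probs > 1)) {
    abort("simulation probabilities must lie in [0, 1]")
  }
  if (abs(sum(params$phenotype_prevalence) - 1) > 1e-8) {
    abort(sprintf("phenotype_prevalence must sum to 1 (got %.4f)",
                  sum(params$phenotype_prevalence)))
  }
  if (abs(sum(params$source_mix) - 1) > 1e-8) {
    abort("source_mix must sum to 1")
  }
  if (params$n_patients < 1) abort("n_patients must be >= 1")
  params
}

#' Named simulation presets
#'
#' `"clean"` turns every noise process off and gives each patient a
#' single recent single-value echo, so the quality-aware pipeline must
#' recover the gold phenotype exactly. `"paper_like"` turns on radiology
#' contamination, nuclear bias, multi-value echoes and coding noise at
#' the package defaults.
#'
#' @param name `"clean"` or `"paper_like"`.
#' @param ... overrides passed to [sim_params()].
#' @return A `hf_sim_params`.
#' @export
sim_preset <- function(name, ...) {
  known <- c("clean", "paper_like")
  if (!name %in% known) {
    abort(sprintf("unknown preset '%s'; available: %s", name,
                  paste(known, collapse = ", ")))
  }
  if (name == "clean") {
    sim_params(studies_min = 1, studies_lambda = 0, recent_only = TRUE,
               source_mix = c(nlp_echo = 1, nlp_note = 0,
                              nlp_radiology = 0, cart = 0),
               p_multi_value_echo = 0, p_radiology_noncardiac = 0,
               p_icd_missing = 0, p_icd_false_positive = 0,
               p_problem_list_active = 1, ...)
  } else {
    sim_params(...)
  }
}

#' Read simulation parameters from YAML
#'
#' @param path YAML file; keys mirror [sim_params()] arguments
#'   (vector-valued keys as maps).
#' @return A `hf_sim_params`.
#' @export
read_sim_params <- function(path) {
  vals <- yaml::read_yaml(path)
  for (key in c("phenotype_prevalence", "source_mix",
                "cart_modality_mix")) {
    if (!is.null(vals[[key]])) vals[[key]] <- unlist(vals[[key]])
  }
  if (!is.null(vals$true_lvef_bands)) {
    vals$true_lvef_bands <- lapply(vals$true_lvef_bands, unlist)
  }
  preset <- vals$preset
  vals$preset <- NULL
  if (!is.null(preset)) {
    do.call(sim_preset, c(list(name = preset), vals))
  } else {
    do.call(sim_params, vals)
  }
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sample_date <- function(n, params) {
  span <- if (params$recent_only) 300L else
    round(params$timeline_years * 365.25)
  params$as_of_date - sample.int(span + 1L, n, replace = TRUE) + 1L
}

render_echo_text <- function(values) {
  if (length(values) == 1) {
    sprintf("LVEF is %d%%.", values)
  } else {
    sprintf("EF %d-%d%%.", values[1], values[2])
  }
}

#' Generate a gold-labeled synthetic cohort
#'
#' @param params a [sim_params()] or [sim_preset()].
#' @return A list: `cohort` (an [hf_cohort()]), `gold` (tibble
#'   `patient_id`, `true_phenotype`, `true_lvef`), `params`.
#'   Deterministic for a given `params$seed`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  params <- validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_patients
  as_of <- params$as_of_date
  ids <- sprintf("P%05d", seq_len(n))
  networks <- c("N1", "N2")
  network <- sample(networks, n, replace = TRUE)
  facility <- paste0(network, "-F", sample.int(2, n, replace = TRUE))
  provider <- paste0(facility, "-D", sample.int(3, n, replace = TRUE))
  roster <- tibble::tibble(patient_id = ids, facility_id = facility,
                           provider_id = provider, network_id = network)

  classes <- names(params$phenotype_prevalence)
  phenotype <- sample(classes, n, replace = TRUE,
                      prob = params$phenotype_prevalence)
  true_lvef <- unname(vapply(phenotype, function(ph) {
    band <- params$true_lvef_bands[[ph]]
    sample(band[1]:band[2], 1)
  }, numeric(1)))
  gold <- tibble::tibble(patient_id = ids, true_phenotype = phenotype,
                         true_lvef = true_lvef)

  diagnoses <- list(); imaging <- list(); cart <- list()
  medications <- list(); admissions <- list(); encounters <- list()
  report_seq <- 0L

  hf_code_for <- function(ph) {
    switch(ph, HFrEF = "I50.22", HFmrEF = "I50.9", HFpEF = "I50.32")
  }

  for (i in seq_len(n)) {
    pid <- ids[i]; ph <- phenotype[i]; ef <- true_lvef[i]

    ## --- diagnoses -----------------------------------------------------
    icd_missing <- runif(1) < params$p_icd_missing
    if (!icd_missing) {
      dx_date <- sample_date(1, params)
      diagnoses[[length(diagnoses) + 1]] <- tibble::tibble(
        patient_id = pid, code = hf_code_for(ph), code_system = "ICD10",
        record_date = dx_date, origin = "encounter", active = NA)
      if (runif(1) < params$p_problem_list_active) {
        diagnoses[[length(diagnoses) + 1]] <- tibble::tibble(
          patient_id = pid, code = hf_code_for(ph), code_system = "ICD10",
          record_date = dx_date, origin = "problem_list", active = TRUE)
      }
    }
    if (runif(1) < params$p_icd_false_positive) {
      diagnoses[[length(diagnoses) + 1]] <- tibble::tibble(
        patient_id = pid, code = "E11.9", code_system = "ICD10",
        record_date = sample_date(1, params), origin = "encounter",
        active = NA)
    }

    ## --- LVEF studies --------------------------------------------------
    n_studies <- params$studies_min + rpois(1, params$studies_lambda)
    for (s in seq_len(n_studies)) {
      src <- sample(names(params$source_mix), 1,
                    prob = params$source_mix)
      sdate <- sample_date(1, params)
      if (src == "cart") {
        modality <- sample(names(params$cart_modality_mix), 1,
                           prob = params$cart_modality_mix)
        value <- ef
        if (modality == "nuclear") {
          value <- round(clip(ef + rnorm(1, params$nuclear_bias,
                                         params$nuclear_sd), 5, 95))
        }
        cart[[length(cart) + 1]] <- tibble::tibble(
          patient_id = pid, record_date = sdate, lvef = value,
          source_modality = modality)
        next
      }
      report_seq <- report_seq + 1L
      rid <- sprintf("R%06d", report_seq)
      if (src == "nlp_echo") {
        if (runif(1) < params$p_multi_value_echo) {
          spread <- sample(1:15, 1)
          values <- sort(clip(c(ef, ef + spread * sample(c(-1, 1), 1)),
                              5, 95))
          text <- render_echo_text(values)
        } else {
          text <- render_echo_text(ef)
        }
        imaging[[length(imaging) + 1]] <- tibble::tibble(
          report_id = rid, patient_id = pid, report_date = sdate,
          source_system = "echo",
          modality_hint = sample(c("TTE", "TEE"), 1, prob = c(0.9, 0.1)),
          text = text)
      } else if (src == "nlp_note") {
        imaging[[length(imaging) + 1]] <- tibble::tibble(
          report_id = rid, patient_id = pid, report_date = sdate,
          source_system = "clinical_note", modality_hint = NA_character_,
          text = sprintf(
            "The left ventricular ejection fraction is estimated at %d%%.",
            ef))
      } else { # nlp_radiology
        if (runif(1) < params$p_radiology_noncardiac) {
          imaging[[length(imaging) + 1]] <- tibble::tibble(
            report_id = rid, patient_id = pid, report_date = sdate,
            source_system = "radiology", modality_hint = "other",
            text = sprintf("Gallbladder ejection fraction of %d%%.",
                           sample(35:95, 1)))
        } else {
          value <- round(clip(ef + rnorm(1, params$nuclear_bias,
                                         params$nuclear_sd), 5, 95))
          imaging[[length(imaging) + 1]] <- tibble::tibble(
            report_id = rid, patient_id = pid, report_date = sdate,
            source_system = "radiology", modality_hint = "nuclear",
            text = sprintf("Ejection fraction %d%%.", value))
        }
      }
    }

    ## --- medications (KPI surface) ------------------------------------
    gdmt <- default_gdmt_classes()[[ph]]
    if (!is.null(gdmt)) {
      for (cl in gdmt) {
        if (runif(1) < params$p_gdmt) {
          drug_idx <- sample.int(length(cl$drugs), 1)
          target <- cl$drugs[[drug_idx]]
          at_target <- runif(1) < params$p_gdmt_target
          medications[[length(medications) + 1]] <- tibble::tibble(
            patient_id = pid, drug_name = names(cl$drugs)[drug_idx],
            dose = if (at_target) target else target / 2,
            dose_unit = "mg",
            start_date = as_of - sample.int(700, 1),
            end_date = as.Date(NA))
        }
      }
    }
    if (runif(1) < params$p_high_risk_med) {
      pool <- c("ibuprofen", "pioglitazone", "diltiazem", "dronedarone")
      medications[[length(medications) + 1]] <- tibble::tibble(
        patient_id = pid, drug_name = sample(pool, 1), dose = 100,
        dose_unit = "mg", start_date = as_of - sample.int(300, 1),
        end_date = as.Date(NA))
    }

    ## --- admissions and encounters ------------------------------------
    n_adm <- rpois(1, params$lambda_hf_admissions)
    if (n_adm > 0) {
      admissions[[length(admissions) + 1]] <- tibble::tibble(
        patient_id = pid,
        admit_date = as_of - sample.int(360, n_adm, replace = TRUE),
        primary_dx_is_hf = TRUE)
    }
    if (runif(1) < params$p_cardiology_encounter) {
      encounters[[length(encounters) + 1]] <- tibble::tibble(
        patient_id = pid,
        encounter_date = as_of - sample.int(360, 1),
        specialty = "cardiology")
    } else {
      encounters[[length(encounters) + 1]] <- tibble::tibble(
        patient_id = pid,
        encounter_date = as_of - sample.int(360, 1),
        specialty = "primary care")
    }
  }

  bind_or_empty <- function(rows, name) {
    if (length(rows) == 0) empty_table(name) else dplyr::bind_rows(rows)
  }
  cohort <- hf_cohort(
    roster = roster,
    diagnoses = bind_or_empty(diagnoses, "diagnoses"),
    imaging = bind_or_empty(imaging, "imaging"),
    cart = bind_or_empty(cart, "cart"),
    medications = bind_or_empty(medications, "medications"),
    admissions = bind_or_empty(admissions, "admissions"),
    encounters = bind_or_empty(encounters, "encounters"))
  list(cohort = cohort, gold = gold, params = params)
}

#' Simulate and write a cohort plus gold labels to a directory
#'
#' @param params a [sim_params()].
#' @param dir output directory.
#' @return Invisibly, the simulation list from [simulate_cohort()].
#' @export
write_simulated_cohort <- function(params, dir) {
  sim <- simulate_cohort(params)
  write_cohort(sim$cohort, dir)
  readr::write_csv(sim$gold, file.path(dir, "gold_labels.csv"))
  invisible(sim)
}
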
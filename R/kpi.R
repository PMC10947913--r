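#' KPI configuration
#'
#' Defaults for guideline-directed medical therapy (GDMT) class
#' membership and target doses are guideline-derived editable defaults,
#' not fixed content of the phenotyping algorithm; sites are expected to
#' adapt them. The high-risk medication lists distinguish drugs harmful
#' in any HF subtype from those contraindicated only in HFrEF.
#'
#' @param gdmt_classes named list: phenotype -> list of class
#'   definitions, each `list(class =, drugs = named numeric vector of
#'   target daily doses in mg)`.
#' @param high_risk_meds_any_hf lower-case drug names flagged for every
#'   HF phenotype.
#' @param high_risk_meds_hfref lower-case drug names flagged only for
#'   HFrEF.
#' @param high_risk_admission_count admissions threshold for the
#'   high-risk KPI (default 2 in the past year).
#' @param cardiology_specialty_labels encounter specialties counting as
#'   cardiology care.
#' @param color_thresholds named list: KPI name -> `list(green_min =,
#'   yellow_min =, direction = "higher"|"lower")`. Unlisted KPIs use
#'   `default`.
#' @return A list of class `hf_kpi_config`.
#' @export
kpi_config <- function(gdmt_classes = default_gdmt_classes(),
                       high_risk_meds_any_hf = c(
                         "ibuprofen", "naproxen", "diclofenac",
                         "meloxicam", "celecoxib", "indomethacin",
                         "ketorolac", "alogliptin", "saxagliptin",
                         "pioglitazone", "rosiglitazone"),
                       high_risk_meds_hfref = c(
                         "cilostazol", "disopyramide", "dronedarone",
                         "flecainide", "propafenone", "diltiazem",
                         "verapamil", "nifedipine"),
                       high_risk_admission_count = 2,
                       cardiology_specialty_labels = c(
                         "cardiology", "heart failure clinic"),
                       color_thresholds = list(
                         default = list(green_min = 80, yellow_min = 60,
                                        direction = "higher"),
                         high_risk = list(green_min = 80, yellow_min = 60,
                                          direction = "lower"),
                         high_risk_meds = list(green_min = 80,
                                               yellow_min = 60,
                                               direction = "lower"))) {
  structure(list(
    gdmt_classes = gdmt_classes,
    high_risk_meds_any_hf = tolower(high_risk_meds_any_hf),
    high_risk_meds_hfref = tolower(high_risk_meds_hfref),
    high_risk_admission_count = high_risk_admission_count,
    cardiology_specialty_labels = tolower(cardiology_specialty_labels),
    color_thresholds = color_thresholds),
    class = "hf_kpi_config")
}

default_gdmt_classes <- function() {
  hfref <- list(
    list(class = "beta_blocker",
         drugs = c("metoprolol succinate" = 200, "carvedilol" = 50,
                   "bisoprolol" = 10)),
    list(class = "raasi",
         drugs = c("lisinopril" = 40, "enalapril" = 40, "losartan" = 150,
                   "valsartan" = 320, "sacubitril/valsartan" = 400)),
    list(class = "mra",
         drugs = c("spironolactone" = 25, "eplerenone" = 50)),
    list(class = "sglt2i",
         drugs = c("dapagliflozin" = 10, "empagliflozin" = 10)))
  sglt2_only <- hfref[4]
  list(HFrEF = hfref, HFmrEF = sglt2_only, HFpEF = sglt2_only)
}

#' Read a KPI configuration from YAML
#'
#' @param path YAML file; keys mirror [kpi_config()] arguments.
#'   `gdmt_classes` is a map phenotype -> list of `{class, drugs}` with
#'   `drugs` a map drug name -> target dose.
#' @return A `hf_kpi_config`.
#' @export
read_kpi_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$gdmt_classes)) {
    vals$gdmt_classes <- lapply(vals$gdmt_classes, function(classes) {
      lapply(classes, function(cl) {
        list(class = cl$class, drugs = unlist(cl$drugs))
      })
    })
  }
  do.call(kpi_config, vals)
}

med_active_on <- function(medications, as_of_date) {
  medications$start_date <= as_of_date &
    (is.na(medications$end_date) | medications$end_date >= as_of_date)
}

#' Is a patient high-risk?
#'
#' High risk means at least `high_risk_admission_count` HF admissions in
#' the past year and receipt of cardiology-specialty services (at least
#' one cardiology encounter) in the same window.
#'
#' @param admissions admission rows for one patient.
#' @param encounters encounter rows for one patient.
#' @param as_of_date reference date.
#' @param cfg a [kpi_config()].
#' @return `TRUE` or `FALSE`.
#' @export
flag_high_risk_patient <- function(admissions, encounters, as_of_date,
                                   cfg = kpi_config()) {
  n_hf <- sum(admissions$primary_dx_is_hf &
              in_window(admissions$admit_date, as_of_date, 1))
  cards <- any(tolower(encounters$specialty) %in%
                 cfg$cardiology_specialty_labels &
               in_window(encounters$encounter_date, as_of_date, 1))
  n_hf >= cfg$high_risk_admission_count && cards
}

#' Is a patient on a targeted high-risk medication?
#'
#' @param medications medication rows for one patient.
#' @param phenotype the patient's phenotype.
#' @param as_of_date reference date (a drug counts if active that day).
#' @param cfg a [kpi_config()].
#' @return `list(flag = logical, matched = character)` naming the
#'   matched drugs. The HFrEF-only list applies only to HFrEF patients.
#' @export
flag_high_risk_meds <- function(medications, phenotype, as_of_date,
                                cfg = kpi_config()) {
  active <- medications[med_active_on(medications, as_of_date), ,
                        drop = FALSE]
  drugs <- tolower(active$drug_name)
  matched <- drugs[drugs %in% cfg$high_risk_meds_any_hf]
  if (identical(phenotype, "HFrEF")) {
    matched <- c(matched, drugs[drugs %in% cfg$high_risk_meds_hfref])
  }
  matched <- unique(matched)
  list(flag = length(matched) > 0, matched = matched)
}

#' GDMT use and target dosing for one patient
#'
#' Evaluates only the classes configured for the patient's phenotype.
#' On-therapy means an active member drug; at-target means the active
#' dose is at or above the configured target. A drug with an
#' unparseable (missing) dose counts as on-therapy but not at target,
#' with a warning.
#'
#' @param medications medication rows for one patient.
#' @param phenotype `"HFrEF"`, `"HFmrEF"` or `"HFpEF"`.
#' @param as_of_date reference date.
#' @param cfg a [kpi_config()].
#' @return A tibble: `class`, `on_therapy`, `at_target`.
#' @export
compute_gdmt_use <- function(medications, phenotype, as_of_date,
                             cfg = kpi_config()) {
  classes <- cfg$gdmt_classes[[phenotype]]
  if (is.null(classes)) {
    return(tibble::tibble(class = character(), on_therapy = logical(),
                          at_target = logical()))
  }
  active <- medications[med_active_on(medications, as_of_date), ,
                        drop = FALSE]
  drugs <- tolower(active$drug_name)
  rows <- lapply(classes, function(cl) {
    members <- tolower(names(cl$drugs))
    idx <- which(drugs %in% members)
    on_therapy <- length(idx) > 0
    at_target <- FALSE
    for (i in idx) {
      target <- cl$drugs[[match(drugs[i], members)]]
      dose <- active$dose[i]
      if (is.na(dose)) {
        warn(sprintf("unparseable dose for %s (patient %s); not at target",
                     active$drug_name[i], active$patient_id[i]))
      } else if (dose >= target) {
        at_target <- TRUE
      }
    }
    tibble::tibble(class = cl$class, on_therapy = on_therapy,
                   at_target = at_target)
  })
  dplyr::bind_rows(rows)
}

#' Per-patient KPI flags for a phenotyped cohort
#'
#' Builds the numerator/denominator membership table feeding
#' [aggregate_kpis()]. KPIs: `high_risk`, `high_risk_meds`,
#' `gdmt_<class>` and `gdmt_<class>_target` for every configured GDMT
#' class. Denominators are the included, classified (non-unspecified)
#' patients; target-dose denominators are the on-therapy patients.
#'
#' @param cohort an [hf_cohort()].
#' @param phenotypes tibble from [phenotype_cohort()].
#' @param as_of_date reference date.
#' @param cfg a [kpi_config()].
#' @return A tibble: `patient_id`, `kpi`, `in_denominator`,
#'   `in_numerator`.
#' @export
compute_kpi_flags <- function(cohort, phenotypes, as_of_date,
                              cfg = kpi_config()) {
  included <- phenotypes[phenotypes$included, , drop = FALSE]
  adm_split <- split(cohort$admissions, cohort$admissions$patient_id)
  enc_split <- split(cohort$encounters, cohort$encounters$patient_id)
  med_split <- split(cohort$medications, cohort$medications$patient_id)
  empty <- function(tbl) tbl[0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(included)), function(i) {
    pid <- included$patient_id[i]
    phen <- included$phenotype[i]
    adm <- adm_split[[pid]] %||% empty(cohort$admissions)
    enc <- enc_split[[pid]] %||% empty(cohort$encounters)
    med <- med_split[[pid]] %||% empty(cohort$medications)
    out <- tibble::tibble(
      patient_id = pid,
      kpi = c("high_risk", "high_risk_meds"),
      in_denominator = TRUE,
      in_numerator = c(
        flag_high_risk_patient(adm, enc, as_of_date, cfg),
        flag_high_risk_meds(med, phen, as_of_date, cfg)$flag))
    if (phen %in% names(cfg$gdmt_classes)) {
      gdmt <- compute_gdmt_use(med, phen, as_of_date, cfg)
      out <- dplyr::bind_rows(out,
        tibble::tibble(patient_id = pid,
                       kpi = paste0("gdmt_", gdmt$class),
                       in_denominator = TRUE,
                       in_numerator = gdmt$on_therapy),
        tibble::tibble(patient_id = pid,
                       kpi = paste0("gdmt_", gdmt$class, "_target"),
                       in_denominator = gdmt$on_therapy,
                       in_numerator = gdmt$at_target))
    }
    out
  })
  dplyr::bind_rows(rows)
}

color_for <- function(kpi, pct, cfg) {
  th <- cfg$color_thresholds[[kpi]] %||% cfg$color_thresholds$default
  if (is.na(pct)) return(NA_character_)
  if (identical(th$direction, "lower")) {
    if (pct <= 100 - th$green_min) "green"
    else if (pct <= 100 - th$yellow_min) "yellow"
    else "red"
  } else {
    if (pct >= th$green_min) "green"
    else if (pct >= th$yellow_min) "yellow"
    else "red"
  }
}

#' Aggregate per-patient KPI flags to reporting levels
#'
#' Exact integer numerators and denominators at provider, facility,
#' network and national level; the national row is always present.
#' Percentage is `100 * numerator / denominator` (`NA` when the
#' denominator is 0, rendered as an em dash downstream); colors come
#' from the configured thresholds.
#'
#' @param flags tibble from [compute_kpi_flags()].
#' @param roster the cohort roster (for unit membership).
#' @param cfg a [kpi_config()].
#' @return A tibble: `level`, `unit_id`, `kpi`, `numerator`,
#'   `denominator`, `pct`, `color`.
#' @export
aggregate_kpis <- function(flags, roster, cfg = kpi_config()) {
  joined <- dplyr::left_join(flags, roster, by = "patient_id")
  level_units <- list(provider = "provider_id", facility = "facility_id",
                      network = "network_id")
  kpis <- sort(unique(flags$kpi))
  out <- list()
  for (level in names(level_units)) {
    unit_col <- level_units[[level]]
    grp <- dplyr::group_by(joined, unit_id = .data[[unit_col]], .data$kpi)
    agg <- dplyr::summarise(grp,
      numerator = sum(.data$in_numerator & .data$in_denominator),
      denominator = sum(.data$in_denominator), .groups = "drop")
    agg$level <- level
    out[[level]] <- agg
  }
  national <- dplyr::summarise(
    dplyr::group_by(joined, .data$kpi),
    numerator = sum(.data$in_numerator & .data$in_denominator),
    denominator = sum(.data$in_denominator), .groups = "drop")
  # national row present even for an empty cohort
  if (nrow(national) == 0 && length(kpis) == 0) {
    national <- tibble::tibble(kpi = "high_risk", numerator = 0L,
                               denominator = 0L)
  }
  national$level <- "national"
  national$unit_id <- "ALL"
  out$national <- national
  report <- dplyr::bind_rows(out)
  report$pct <- ifelse(report$denominator > 0,
                       100 * report$numerator / report$denominator,
                       NA_real_)
  report$color <- vapply(seq_len(nrow(report)), function(i) {
    color_for(report$kpi[i], report$pct[i], cfg)
  }, character(1))
  cols <- c("level", "unit_id", "kpi", "numerator", "denominator",
            "pct", "color")
  dplyr::arrange(report[cols],
                 factor(.data$level,
                        levels = c("provider", "facility", "network",
                                   "national")),
                 .data$unit_id, .data$kpi)
}

#' Write a KPI report as CSV and JSON
#'
#' @param report tibble from [aggregate_kpis()].
#' @param csv_path,json_path output files (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_kpi_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(report, csv_path, na = "")
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, dataframe = "rows",
                         na = "null", auto_unbox = FALSE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}
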
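#' Classification configuration
#'
#' Houses every numeric constant of the phenotyping algorithm.
#' Lookback windows are calendar-anniversary based and inclusive at the
#' old boundary: an item dated exactly `lookback_years` before
#' `as_of_date` is in the window.
#'
#' @param as_of_date reference date for all windows (Date or ISO string).
#' @param lookback_years evidence older than this is ignored (default 3).
#' @param high_quality_priority_years a high-tier study within this
#'   window pre-empts anything more recent of lower quality (default 1).
#' @param multi_value_avg_threshold max spread (percentage points)
#'   between the high and low of a multi-value study for the average to
#'   be used; above it the high value alone is used (default 10).
#' @param implausible_value_threshold any pooled value above this during
#'   multi-value resolution marks the patient unspecified (default 75).
#' @param hfref_max upper LVEF bound (inclusive) for HFrEF (default 40).
#' @param hfmref_max upper LVEF bound (inclusive, integer reading) for
#'   HFmrEF (default 49); HFpEF is `>= hfmref_max + 1`.
#' @param hf_code_prefixes ICD code prefixes defining documented HF
#'   (default `I50` and `428`).
#' @param icd_fallback_map legacy-mode ICD-only classification: named
#'   list of code-prefix vectors for `HFrEF` (systolic codes) and
#'   `HFpEF` (diastolic codes).
#' @return A list of class `hf_classification_config`.
#' @export
classification_config <- function(as_of_date = Sys.Date(),
                                  lookback_years = 3,
                                  high_quality_priority_years = 1,
                                  multi_value_avg_threshold = 10,
                                  implausible_value_threshold = 75,
                                  hfref_max = 40,
                                  hfmref_max = 49,
                                  hf_code_prefixes = c("I50", "428"),
                                  icd_fallback_map = list(
                                    HFrEF = c("I50.2", "I50.4", "428.2", "428.4"),
                                    HFpEF = c("I50.3", "428.3"))) {
  as_of_date <- as_iso_date(as_of_date, "as_of_date")
  stopifnot(hfref_max > 0, hfref_max < hfmref_max, hfmref_max < 100,
            high_quality_priority_years <= lookback_years)
  structure(list(as_of_date = as_of_date,
                 lookback_years = lookback_years,
                 high_quality_priority_years = high_quality_priority_years,
                 multi_value_avg_threshold = multi_value_avg_threshold,
                 implausible_value_threshold = implausible_value_threshold,
                 hfref_max = hfref_max,
                 hfmref_max = hfmref_max,
                 hf_code_prefixes = hf_code_prefixes,
                 icd_fallback_map = icd_fallback_map),
            class = "hf_classification_config")
}

#' Read a classification configuration from YAML
#'
#' Keys mirror the arguments of [classification_config()]; absent keys
#' keep their defaults.
#'
#' @param path YAML file.
#' @return A `hf_classification_config`.
#' @export
read_classification_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(classification_config, vals)
}

#' Resolve a multi-value LVEF set to one value
#'
#' When a single study carries several LVEF values: any value above the
#' implausibility threshold marks the patient unspecified; otherwise, if
#' the spread between the high and low values is at most
#' `multi_value_avg_threshold` points their average is used, and if it
#' is larger the high value alone is used.
#'
#' @param values numeric vector of at least 2 LVEF percentages.
#' @param cfg a [classification_config()].
#' @return The resolved LVEF (numeric) or the string
#'   `"unspecified_implausible"`.
#' @export
resolve_multi_value <- function(values, cfg = classification_config()) {
  if (length(values) < 2) {
    abort("resolve_multi_value requires at least 2 values")
  }
  if (any(values > cfg$implausible_value_threshold)) {
    return("unspecified_implausible")
  }
  spread <- max(values) - min(values)
  if (spread <= cfg$multi_value_avg_threshold) {
    (max(values) + min(values)) / 2
  } else {
    max(values)
  }
}

selection_result <- function(patient_id, effective_lvef, verdict,
                             chosen_items, rule_fired) {
  tibble::tibble(patient_id = patient_id,
                 effective_lvef = effective_lvef,
                 verdict = verdict,
                 chosen_items = list(chosen_items),
                 rule_fired = rule_fired)
}

#' Select the effective LVEF for one patient (quality-aware algorithm)
#'
#' The hierarchical cascade: (1) restrict to non-excluded evidence in
#' the lookback window; none leaves the patient unspecified for lack of
#' data. (2) A high-quality study within the priority window (default 1
#' year) pre-empts everything else; the candidate set is the high-tier
#' items on the most recent such date. Otherwise the candidates are the
#' items on the most recent date in the lookback window, high tier
#' preferred when both tiers share that date. (3) Same-date single-value
#' candidates that individually fall in both the reduced and the
#' preserved class are a conflict: the patient cannot be both HFrEF and
#' HFpEF. (4) All candidate values pool; one value is used directly,
#' several go through [resolve_multi_value()].
#'
#' @param evidence evidence rows for one patient ([build_evidence()]).
#' @param cfg a [classification_config()].
#' @return A one-row tibble: `patient_id`, `effective_lvef` (`NA` unless
#'   `verdict == "value"`), `verdict` (`"value"`,
#'   `"unspecified_conflict"`, `"unspecified_implausible"`,
#'   `"unspecified_no_data"`), `chosen_items` (list column, audit),
#'   `rule_fired`.
#' @export
select_effective_lvef <- function(evidence, cfg = classification_config()) {
  pid <- if (nrow(evidence) > 0) evidence$patient_id[1] else NA_character_
  usable <- evidence[evidence$tier != "excluded" &
                     in_window(evidence$event_date, cfg$as_of_date,
                               cfg$lookback_years), , drop = FALSE]
  if (nrow(usable) == 0) {
    return(selection_result(pid, NA_real_, "unspecified_no_data",
                            NULL, "no_data"))
  }
  high_recent <- usable[usable$tier == "high" &
                        in_window(usable$event_date, cfg$as_of_date,
                                  cfg$high_quality_priority_years), ,
                        drop = FALSE]
  if (nrow(high_recent) > 0) {
    chosen_date <- max(high_recent$event_date)
    candidates <- high_recent[high_recent$event_date == chosen_date, ,
                              drop = FALSE]
    rule <- "high_quality_within_priority_window"
  } else {
    chosen_date <- max(usable$event_date)
    candidates <- usable[usable$event_date == chosen_date, , drop = FALSE]
    if (any(candidates$tier == "high")) {
      candidates <- candidates[candidates$tier == "high", , drop = FALSE]
    }
    rule <- "most_recent_in_lookback"
  }
  # conflict: distinct single-value studies on the chosen date individually
  # supporting both a reduced and a preserved phenotype
  singles <- unlist(candidates$values[candidates$n_values == 1])
  if (length(singles) >= 2 &&
      any(singles <= cfg$hfref_max) &&
      any(singles >= cfg$hfmref_max + 1)) {
    return(selection_result(pid, NA_real_, "unspecified_conflict",
                            candidates, "same_date_conflict"))
  }
  pooled <- unlist(candidates$values)
  if (length(pooled) == 1) {
    return(selection_result(pid, pooled, "value", candidates,
                            paste0(rule, "/single_value")))
  }
  resolved <- resolve_multi_value(pooled, cfg)
  if (identical(resolved, "unspecified_implausible")) {
    return(selection_result(pid, NA_real_, "unspecified_implausible",
                            candidates, paste0(rule, "/implausible_value")))
  }
  selection_result(pid, resolved, "value", candidates,
                   paste0(rule, "/multi_value_resolved"))
}

#' Select the effective LVEF, legacy mode (lowest from any source)
#'
#' The legacy algorithm ignores source quality entirely: the effective
#' LVEF is the minimum over every value of every evidence item —
#' excluded tiers included — within the lookback window. No multi-value
#' or conflict logic applies.
#'
#' @inheritParams select_effective_lvef
#' @return A one-row tibble as for [select_effective_lvef()].
#' @export
select_effective_lvef_v1 <- function(evidence,
                                     cfg = classification_config()) {
  pid <- if (nrow(evidence) > 0) evidence$patient_id[1] else NA_character_
  usable <- evidence[in_window(evidence$event_date, cfg$as_of_date,
                               cfg$lookback_years), , drop = FALSE]
  values <- unlist(usable$values)
  if (length(values) == 0) {
    return(selection_result(pid, NA_real_, "unspecified_no_data",
                            NULL, "no_data"))
  }
  lowest <- min(values)
  chosen <- usable[vapply(usable$values, function(v) lowest %in% v,
                          logical(1)), , drop = FALSE]
  selection_result(pid, lowest, "value", chosen, "lowest_any_source")
}
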
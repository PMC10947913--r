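#' Default LVEF extraction patterns
#'
#' The extractor is a deterministic pattern matcher, not a full clinical
#' NLP system: it finds ejection-fraction phrases, pulls the numeric
#' value (or both endpoints of a range), rescales decimal fractions in
#' (0, 1] to percent, and flags mentions whose local context names a
#' non-left-ventricular ejection fraction (gallbladder, right ventricle).
#' Qualitative statements ("normal LV systolic function") yield no
#' numeric mention.
#'
#' @param path optional YAML file overriding any of the keys
#'   `lv_context`, `value`, `range_sep`, `non_cardiac_context` (each a
#'   character vector of regular expressions).
#' @return A named list of pattern vectors.
#' @export
lvef_patterns <- function(path = NULL) {
  patterns <- list(
    # phrases that introduce an ejection-fraction value
    lv_context = c(
      "left\\s+ventricular\\s+ejection\\s+fraction",
      "lv\\s+ejection\\s+fraction",
      "ejection\\s+fraction",
      "\\blvef\\b",
      "\\bef\\b"),
    # a number, optionally decimal
    value = "[0-9]+(?:\\.[0-9]+)?",
    # separators joining the two endpoints of a range
    range_sep = c("-", "–", "\\bto\\b"),
    # context words marking a non-LV ejection fraction
    non_cardiac_context = c(
      "gall\\s*-?\\s*bladder",
      "right\\s+ventricular",
      "\\brvef\\b"))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (key in names(user)) patterns[[key]] <- user[[key]]
  }
  patterns
}

# One combined regex: EF phrase, a short gap without digits or other
# sentence content, a value, and optionally "sep value" for a range.
build_mention_regex <- function(patterns) {
  ctx <- paste0("(?:", paste(patterns$lv_context, collapse = "|"), ")")
  val <- paste0("(", patterns$value, ")")
  sep <- paste0("(?:", paste(patterns$range_sep, collapse = "|"), ")")
  paste0("(?i)", ctx, "[^0-9%\\.]{0,25}", val,
         "(?:\\s*", sep, "\\s*(", patterns$value, "))?",
         "\\s*(?:%|percent)?")
}

#' Extract LVEF mentions from one free-text report
#'
#' @param report a one-row imaging-report tibble (or list) with at least
#'   `report_id` and `text`.
#' @param patterns pattern set from [lvef_patterns()].
#' @return A list with `report_id`, `values` (numeric, document order),
#'   `raw_spans` (matched snippets) and `non_cardiac` (logical), or
#'   `NULL` when the text contains no ejection-fraction value. Values
#'   outside (0, 100] after fraction rescaling are discarded with a
#'   warning. When a report mixes cardiac and non-cardiac mentions, only
#'   the cardiac values are kept; `non_cardiac = TRUE` only when every
#'   mention is non-cardiac.
#' @export
extract_lvef <- function(report, patterns = lvef_patterns()) {
  text <- report$text
  if (is.null(text) || length(text) == 0 || is.na(text) || text == "") {
    return(NULL)
  }
  rx <- build_mention_regex(patterns)
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  spans <- regmatches(text, list(m))[[1]]
  starts <- as.integer(m)
  nc_rx <- paste0("(?i)(?:", paste(patterns$non_cardiac_context,
                                   collapse = "|"), ")\\s*$")
  values <- list()
  span_out <- character(0)
  cardiac <- logical(0)
  for (i in seq_along(spans)) {
    nums <- regmatches(spans[i],
                       gregexpr("[0-9]+(?:\\.[0-9]+)?", spans[i],
                                perl = TRUE))[[1]]
    vals <- as.numeric(nums)
    vals <- ifelse(vals > 0 & vals <= 1, round(vals * 100, 4), vals)
    ok <- vals > 0 & vals <= 100
    if (any(!ok)) {
      warn(sprintf("discarding out-of-range EF value(s) %s in report %s",
                   paste(vals[!ok], collapse = ", "),
                   report$report_id %||% "<unknown>"))
      vals <- vals[ok]
    }
    if (length(vals) == 0) next
    # non-cardiac if the 30 chars before the EF phrase name another organ
    prefix <- substr(text, max(1L, starts[i] - 30L), starts[i] - 1L)
    is_nc <- grepl(nc_rx, prefix, perl = TRUE)
    values <- c(values, list(vals))
    span_out <- c(span_out, spans[i])
    cardiac <- c(cardiac, !is_nc)
  }
  if (length(values) == 0) return(NULL)
  keep <- if (any(cardiac)) cardiac else !cardiac
  list(report_id = report$report_id %||% NA_character_,
       values = unlist(values[keep]),
       raw_spans = span_out[keep],
       non_cardiac = !any(cardiac))
}

fuzz_templates <- list(
  list(kind = "single",
       render = function(v) sprintf("LVEF is %s%%.", v[1])),
  list(kind = "single",
       render = function(v)
         sprintf("The left ventricular ejection fraction is estimated at %s%%.",
                 v[1])),
  list(kind = "range",
       render = function(v) sprintf("EF %s-%s%%.", v[1], v[2])),
  list(kind = "range",
       render = function(v)
         sprintf("Ejection fraction %s to %s percent.", v[1], v[2])),
  list(kind = "range",
       render = function(v)
         sprintf("LVEF %s–%s%% by biplane method.", v[1], v[2])),
  list(kind = "fraction",
       render = function(v) sprintf("Ejection fraction %.2f.", v[1] / 100)),
  list(kind = "qualitative",
       render = function(v)
         "Normal left ventricular size and systolic function."),
  list(kind = "qualitative",
       render = function(v)
         "Moderately reduced LV systolic function; no quantitative estimate."),
  list(kind = "non_cardiac",
       render = function(v)
         sprintf("Gallbladder ejection fraction of %s%%.", v[1])),
  list(kind = "pair",
       render = function(v)
         sprintf("LVEF %s%%. Repeat measurement: EF %s%%.", v[1], v[2]))
)

#' Generate seeded fuzz reports with known expected extractions
#'
#' Emits `(report, expected)` pairs drawn from a template bank covering
#' single values, ranges (three separators), decimal fractions,
#' qualitative-only text, gallbladder decoys, and two-phrase reports.
#' The expectation is computed from template knowledge at render time,
#' independently of the extractor.
#'
#' @param n number of reports (>= 1).
#' @param seed integer seed; output is deterministic for a seed.
#' @return A list of `n` elements, each with `report` (a one-row tibble
#'   in the imaging schema) and `expected` (an LVEF mention as returned
#'   by [extract_lvef()], or `NULL`).
#' @export
fuzz_reports <- function(n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tmpl <- fuzz_templates[[sample.int(length(fuzz_templates), 1)]]
    v1 <- sample(5:74, 1)
    v2 <- v1 + sample(1:15, 1)
    vals <- c(v1, min(v2, 95))
    text <- tmpl$render(vals)
    report_id <- sprintf("FZ%04d", i)
    expected <- switch(tmpl$kind,
      single = list(report_id = report_id, values = vals[1],
                    non_cardiac = FALSE),
      range = list(report_id = report_id, values = vals,
                   non_cardiac = FALSE),
      fraction = list(report_id = report_id, values = vals[1],
                      non_cardiac = FALSE),
      pair = list(report_id = report_id, values = vals,
                  non_cardiac = FALSE),
      non_cardiac = list(report_id = report_id, values = vals[1],
                         non_cardiac = TRUE),
      qualitative = NULL)
    out[[i]] <- list(
      report = tibble::tibble(
        report_id = report_id, patient_id = NA_character_,
        report_date = as.Date(NA), source_system = "echo",
        modality_hint = NA_character_, text = text),
      expected = expected)
  }
  out
}
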
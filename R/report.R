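#' Actionable patients per KPI
#'
#' For "higher is better" KPIs (GDMT uptake) the actionable patients
#' are those in the denominator but missing from the numerator; for
#' "lower is better" KPIs (high-risk state, high-risk medications) they
#' are the flagged patients themselves.
#'
#' @param flags tibble from [compute_kpi_flags()].
#' @param cfg a [kpi_config()].
#' @return A tibble: `kpi`, `patient_id` (each pair at most once).
#' @export
actionable_patients <- function(flags, cfg = kpi_config()) {
  rows <- lapply(sort(unique(flags$kpi)), function(kpi) {
    th <- cfg$color_thresholds[[kpi]] %||% cfg$color_thresholds$default
    sub <- flags[flags$kpi == kpi & flags$in_denominator, , drop = FALSE]
    pids <- if (identical(th$direction, "lower")) {
      sub$patient_id[sub$in_numerator]
    } else {
      sub$patient_id[!sub$in_numerator]
    }
    if (length(pids) == 0) return(NULL)
    tibble::tibble(kpi = kpi, patient_id = sort(unique(pids)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(kpi = character(), patient_id = character())
  }
  out
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_pct <- function(pct) {
  ifelse(is.na(pct), "&mdash;", sprintf("%.1f%%", pct))
}

#' Render a static HTML dashboard
#'
#' Self-contained HTML (inline CSS, no network): one KPI table per
#' facility with the national row for comparison, red/yellow/green cell
#' coloring, and per-KPI anchor links to the actionable patient list.
#'
#' @param kpi_report tibble from [aggregate_kpis()].
#' @param actionable tibble from [actionable_patients()].
#' @param path output HTML file.
#' @param title page title.
#' @return Invisibly, `path`.
#' @export
render_dashboard <- function(kpi_report, actionable, path,
                             title = "Heart Failure Dashboard") {
  css <- paste(
    "body{font-family:sans-serif;margin:2em;}",
    "table{border-collapse:collapse;margin-bottom:2em;}",
    "td,th{border:1px solid #999;padding:4px 10px;}",
    "td.green{background:#c8e6c9;} td.yellow{background:#fff9c4;}",
    "td.red{background:#ffcdd2;} td.na{background:#eee;}",
    ".patients{font-family:monospace;}")
  lines <- c("<!DOCTYPE html>", "<html><head>",
             "<meta charset=\"utf-8\">",
             sprintf("<title>%s</title>", html_escape(title)),
             sprintf("<style>%s</style>", css),
             "</head><body>",
             sprintf("<h1>%s</h1>", html_escape(title)))
  if (nrow(kpi_report) == 0 ||
      all(kpi_report$denominator == 0)) {
    lines <- c(lines, "<p>No patients to display.</p>")
  } else {
    kpis <- sort(unique(kpi_report$kpi))
    national <- kpi_report[kpi_report$level == "national", , drop = FALSE]
    units <- kpi_report[kpi_report$level == "facility", , drop = FALSE]
    row_html <- function(label, sub) {
      cells <- vapply(kpis, function(kpi) {
        r <- sub[sub$kpi == kpi, , drop = FALSE]
        if (nrow(r) == 0 || is.na(r$pct[1])) {
          return("<td class=\"na\">&mdash;</td>")
        }
        sprintf("<td class=\"%s\">%s (%d/%d)</td>", r$color[1],
                fmt_pct(r$pct[1]), r$numerator[1], r$denominator[1])
      }, character(1))
      sprintf("<tr><th>%s</th>%s</tr>", html_escape(label),
              paste(cells, collapse = ""))
    }
    header <- sprintf(
      "<tr><th>Unit</th>%s</tr>",
      paste(sprintf("<th><a href=\"#kpi-%s\">%s</a></th>", kpis, kpis),
            collapse = ""))
    body_rows <- vapply(sort(unique(units$unit_id)), function(u) {
      row_html(u, units[units$unit_id == u, , drop = FALSE])
    }, character(1))
    lines <- c(lines, "<h2>Facilities</h2>", "<table>", header,
               body_rows, row_html("National", national), "</table>",
               "<h2>Actionable patients</h2>")
    for (kpi in kpis) {
      pids <- actionable$patient_id[actionable$kpi == kpi]
      lines <- c(lines,
                 sprintf("<h3 id=\"kpi-%s\">%s</h3>", kpi, kpi),
                 sprintf("<p class=\"patients\">%s</p>",
                         if (length(pids) == 0) "none"
                         else paste(html_escape(pids), collapse = ", ")))
    }
  }
  lines <- c(lines, "</body></html>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Run the full pipeline over a cohort directory
#'
#' Convenience wrapper chaining read, extraction, evidence building,
#' phenotyping, KPI scoring and (optionally) evaluation against a
#' `gold_labels.csv` in the input directory.
#'
#' @param in_dir cohort directory ([write_cohort()] layout).
#' @param cfg a [classification_config()].
#' @param kpi_cfg a [kpi_config()].
#' @param version `"v1"` or `"v2"`.
#' @param patterns pattern set from [lvef_patterns()].
#' @return A list: `cohort`, `evidence`, `phenotypes`, `flags`,
#'   `kpi_report`, and `gold` when gold labels are present.
#' @export
run_pipeline <- function(in_dir, cfg = classification_config(),
                         kpi_cfg = kpi_config(),
                         version = c("v2", "v1"),
                         patterns = lvef_patterns()) {
  version <- match.arg(version)
  cohort <- read_cohort(in_dir)
  evidence <- build_evidence(cohort, patterns)
  phenotypes <- phenotype_cohort(cohort, cfg, version, evidence)
  flags <- compute_kpi_flags(cohort, phenotypes, cfg$as_of_date, kpi_cfg)
  kpi_report <- aggregate_kpis(flags, cohort$roster, kpi_cfg)
  out <- list(cohort = cohort, evidence = evidence,
              phenotypes = phenotypes, flags = flags,
              kpi_report = kpi_report)
  gold_path <- file.path(in_dir, "gold_labels.csv")
  if (file.exists(gold_path)) {
    out$gold <- readr::read_csv(gold_path, col_types = "ccd",
                                progress = FALSE)
  }
  out
}
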
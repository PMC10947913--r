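test_that("the rendered dashboard colors cells and lists actionable patients once", {
  sim <- simulate_cohort(sim_preset("paper_like", n_patients = 60,
                                    seed = 13))
  cfg <- classification_config(as_of_date = sim$params$as_of_date)
  kcfg <- kpi_config()
  ph <- phenotype_cohort(sim$cohort, cfg, "v2")
  flags <- compute_kpi_flags(sim$cohort, ph, cfg$as_of_date, kcfg)
  report <- aggregate_kpis(flags, sim$cohort$roster, kcfg)
  act <- actionable_patients(flags, kcfg)
  expect_equal(anyDuplicated(act[c("kpi", "patient_id")]), 0)
  # cross-check one KPI against the raw flags
  bb <- flags[flags$kpi == "gdmt_beta_blocker" & flags$in_denominator, ]
  expect_setequal(act$patient_id[act$kpi == "gdmt_beta_blocker"],
                  bb$patient_id[!bb$in_numerator])
  path <- withr::local_tempfile(fileext = ".html")
  render_dashboard(report, act, path)
  html <- paste(readLines(path, warn = FALSE), collapse = "\n")
  expect_match(html, "<td class=\"(green|yellow|red)\"")
  expect_match(html, "id=\"kpi-gdmt_beta_blocker\"")
  for (pid in act$patient_id[act$kpi == "high_risk"]) {
    expect_match(html, pid)
  }
})

test_that("a 100% KPI renders green under the default thresholds", {
  roster <- mk_roster("P1")
  flags <- tibble::tibble(patient_id = "P1", kpi = "gdmt_mra",
                          in_denominator = TRUE, in_numerator = TRUE)
  kcfg <- kpi_config()
  report <- aggregate_kpis(flags, roster, kcfg)
  path <- withr::local_tempfile(fileext = ".html")
  render_dashboard(report, actionable_patients(flags, kcfg), path)
  html <- paste(readLines(path, warn = FALSE), collapse = "\n")
  expect_match(html, "<td class=\"green\">100.0%")
})

test_that("an empty cohort renders a valid page with a notice", {
  kcfg <- kpi_config()
  report <- aggregate_kpis(
    tibble::tibble(patient_id = character(), kpi = character(),
                   in_denominator = logical(), in_numerator = logical()),
    mk_roster(character(0)), kcfg)
  path <- withr::local_tempfile(fileext = ".html")
  render_dashboard(report, actionable_patients(report[0, ], kcfg), path)
  html <- paste(readLines(path, warn = FALSE), collapse = "\n")
  expect_match(html, "No patients")
  expect_match(html, "</html>")
})

test_that("the command-line interface runs end to end deterministically", {
  cli <- system.file("cli", "hfdash.R", package = "hfdash")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  run <- function(...) {
    system2("Rscript", c(cli, ...), stdout = TRUE, stderr = TRUE)
  }
  cohort_dir <- file.path(dir, "cohort")
  params <- file.path(dir, "params.yaml")
  writeLines(c("preset: paper_like", "n_patients: 60"), params)
  run("simulate", "--params", params, "--out", cohort_dir,
      "--seed", "17")
  expect_true(file.exists(file.path(cohort_dir, "roster.csv")))
  p1 <- file.path(dir, "ph1.csv"); p2 <- file.path(dir, "ph2.csv")
  run("classify", "--in", cohort_dir, "--out", p1, "--as-of",
      "2022-07-01")
  run("classify", "--in", cohort_dir, "--out", p2, "--as-of",
      "2022-07-01")
  expect_identical(readLines(p1), readLines(p2))
  ev <- file.path(dir, "evaluation.csv")
  run("evaluate", "--in", cohort_dir, "--out", ev, "--as-of",
      "2022-07-01")
  eval_tbl <- readr::read_csv(ev, show_col_types = FALSE)
  expect_setequal(eval_tbl$version, c("v1", "v2"))
  html <- file.path(dir, "dash.html")
  run("report", "--in", cohort_dir, "--out", html, "--as-of",
      "2022-07-01")
  expect_true(file.exists(html))
  # malformed YAML exits with status 2 and names the file
  bad <- file.path(dir, "bad.yaml")
  writeLines("n_patients: [unclosed", bad)
  status <- suppressWarnings(
    system2("Rscript", c(cli, "simulate", "--params", bad, "--out",
                         file.path(dir, "x")),
            stdout = FALSE, stderr = FALSE))
  expect_equal(status, 2)
})
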
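KCFG <- kpi_config()

test_that("high-risk status needs both the admissions and the cardiology criterion", {
  two_adm <- dplyr::bind_rows(mk_adm(days_ago = 30),
                              mk_adm(days_ago = 200))
  cards <- mk_enc(days_ago = 60)
  expect_true(flag_high_risk_patient(two_adm, cards, AS_OF, KCFG))
  three_adm <- dplyr::bind_rows(two_adm, mk_adm(days_ago = 100))
  expect_false(flag_high_risk_patient(three_adm, no_enc(), AS_OF, KCFG))
  expect_false(flag_high_risk_patient(mk_adm(days_ago = 30), cards,
                                      AS_OF, KCFG))
  # admissions older than a year or without an HF primary diagnosis
  # do not count
  stale <- dplyr::bind_rows(mk_adm(days_ago = 30),
                            mk_adm(days_ago = 400),
                            mk_adm(days_ago = 10, hf = FALSE))
  expect_false(flag_high_risk_patient(stale, cards, AS_OF, KCFG))
})

test_that("the HFrEF-only medication list applies only to HFrEF", {
  diltiazem <- mk_med(drug = "Diltiazem", dose = 120)
  expect_false(flag_high_risk_meds(diltiazem, "HFpEF", AS_OF, KCFG)$flag)
  res <- flag_high_risk_meds(diltiazem, "HFrEF", AS_OF, KCFG)
  expect_true(res$flag)
  expect_equal(res$matched, "diltiazem")
  pio <- mk_med(drug = "pioglitazone", dose = 30)
  for (phenotype in c("HFrEF", "HFmrEF", "HFpEF")) {
    expect_true(flag_high_risk_meds(pio, phenotype, AS_OF, KCFG)$flag,
                info = phenotype)
  }
  # a medication that ended before the reference date does not count
  old <- mk_med(drug = "diltiazem", dose = 120, start_days_ago = 300,
                end_days_ago = 100)
  expect_false(flag_high_risk_meds(old, "HFrEF", AS_OF, KCFG)$flag)
})

test_that("GDMT use and target dosing are evaluated per configured class", {
  meds <- dplyr::bind_rows(
    mk_med(drug = "Metoprolol Succinate", dose = 200),
    mk_med(drug = "lisinopril", dose = 10))
  gdmt <- compute_gdmt_use(meds, "HFrEF", AS_OF, KCFG)
  expect_setequal(gdmt$class, c("beta_blocker", "raasi", "mra", "sglt2i"))
  bb <- gdmt[gdmt$class == "beta_blocker", ]
  expect_true(bb$on_therapy); expect_true(bb$at_target)
  ra <- gdmt[gdmt$class == "raasi", ]
  expect_true(ra$on_therapy); expect_false(ra$at_target)
  expect_false(any(gdmt$on_therapy[gdmt$class %in% c("mra", "sglt2i")]))
  # HFpEF evaluates only its configured classes
  expect_identical(compute_gdmt_use(no_meds(), "HFpEF", AS_OF,
                                    KCFG)$class, "sglt2i")
})

test_that("an unparseable dose counts as on-therapy but not at target", {
  meds <- mk_med(drug = "carvedilol", dose = NA)
  expect_warning(gdmt <- compute_gdmt_use(meds, "HFrEF", AS_OF, KCFG),
                 "unparseable dose")
  bb <- gdmt[gdmt$class == "beta_blocker", ]
  expect_true(bb$on_therapy)
  expect_false(bb$at_target)
})

test_that("small hand-built aggregation reproduces exact fractions", {
  roster <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    provider_id = c("D1", "D1", "D2"),
    facility_id = "F1", network_id = "N1")
  flags <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    kpi = "gdmt_beta_blocker",
    in_denominator = TRUE,
    in_numerator = c(TRUE, FALSE, TRUE))
  report <- aggregate_kpis(flags, roster, KCFG)
  fac <- report[report$level == "facility", ]
  expect_equal(fac$numerator, 2)
  expect_equal(fac$denominator, 3)
  expect_equal(fac$pct, 200 / 3)
  nat <- report[report$level == "national", ]
  expect_equal(nat$numerator, 2)
  expect_identical(nat$unit_id, "ALL")
})

test_that("an empty denominator renders as undefined, never as 0%", {
  roster <- mk_roster("P1")
  flags <- tibble::tibble(patient_id = "P1", kpi = "gdmt_sglt2i_target",
                          in_denominator = FALSE, in_numerator = FALSE)
  report <- aggregate_kpis(flags, roster, KCFG)
  expect_true(all(is.na(report$pct)))
  expect_true(all(is.na(report$color)))
})

test_that("numerators and denominators are conserved across levels", {
  set.seed(61)
  kpis <- c("high_risk", "gdmt_beta_blocker", "gdmt_beta_blocker_target")
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    roster <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      provider_id = sample(sprintf("D%d", 1:5), n, replace = TRUE),
      facility_id = sample(sprintf("F%d", 1:3), n, replace = TRUE),
      network_id = sample(sprintf("N%d", 1:2), n, replace = TRUE))
    flags <- tidyr::expand_grid(patient_id = roster$patient_id,
                                kpi = kpis)
    flags$in_denominator <- runif(nrow(flags)) < 0.8
    flags$in_numerator <- flags$in_denominator &
      runif(nrow(flags)) < 0.5
    report <- aggregate_kpis(flags, roster, KCFG)
    for (kpi in kpis) {
      sub <- report[report$kpi == kpi, ]
      nat <- sub[sub$level == "national", ]
      for (level in c("provider", "facility", "network")) {
        lvl <- sub[sub$level == level, ]
        expect_equal(sum(lvl$numerator), nat$numerator)
        expect_equal(sum(lvl$denominator), nat$denominator)
      }
    }
    expect_true(all(report$pct >= 0 & report$pct <= 100, na.rm = TRUE))
  }
})

test_that("colors are monotone in the percentage for higher-is-better KPIs", {
  pcts <- c(0, 59.9, 60, 79.9, 80, 100)
  colors <- vapply(pcts, function(p)
    hfdash:::color_for("gdmt_mra", p, KCFG), character(1))
  expect_identical(colors,
                   c("red", "red", "yellow", "yellow", "green", "green"))
  # lower-is-better KPIs invert the scale
  expect_identical(hfdash:::color_for("high_risk_meds", 10, KCFG),
                   "green")
  expect_identical(hfdash:::color_for("high_risk_meds", 90, KCFG), "red")
})
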
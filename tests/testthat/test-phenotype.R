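test_that("documented HF requires an encounter code or an active problem-list entry", {
  expect_true(has_documented_hf(
    mk_dx(code = "I50.22", origin = "problem_list", active = TRUE), CFG))
  expect_false(has_documented_hf(
    mk_dx(code = "I50.22", origin = "problem_list", active = FALSE), CFG))
  expect_true(has_documented_hf(
    mk_dx(code = "I50.9", days_ago = 730), CFG))
  expect_true(has_documented_hf(
    mk_dx(code = "428.0", code_system = "ICD9"), CFG))
  expect_false(has_documented_hf(mk_dx(code = "E11.9"), CFG))
  expect_false(has_documented_hf(no_dx(), CFG))
  # encounter codes dated after the reference date do not count
  expect_false(has_documented_hf(mk_dx(code = "I50.9", days_ago = -10),
                                 CFG))
})

test_that("LVEF classification uses the guideline bands", {
  expect_identical(classify_lvef(40, CFG), "HFrEF")
  expect_identical(classify_lvef(41, CFG), "HFmrEF")
  expect_identical(classify_lvef(49, CFG), "HFmrEF")
  expect_identical(classify_lvef(50, CFG), "HFpEF")
  expect_identical(classify_lvef(40.5, CFG), "HFmrEF")
  expect_identical(classify_lvef(49.5, CFG), "HFmrEF")
  expect_identical(classify_lvef(15, CFG), "HFrEF")
  expect_identical(classify_lvef(80, CFG), "HFpEF")
  expect_error(classify_lvef(0, CFG))
  expect_error(classify_lvef(101, CFG))
})

test_that("patients without documented HF are excluded in both versions", {
  evidence <- mk_item(days_ago = 100, values = 35)
  for (version in c("v1", "v2")) {
    res <- phenotype_patient(evidence, no_dx(), CFG, version,
                             patient_id = "P1")
    expect_false(res$included)
    expect_true(is.na(res$phenotype))
  }
})

test_that("the documented failure mode: old low-quality low value flips v1 only", {
  evidence <- mk_items(
    mk_item(days_ago = 100, values = 55, tier = "high"),
    mk_item(days_ago = 700, values = 30, tier = "excluded",
            provenance = "nlp_radiology", modality = "other"))
  dx <- mk_dx(code = "I50.9")
  v1 <- phenotype_patient(evidence, dx, CFG, "v1")
  v2 <- phenotype_patient(evidence, dx, CFG, "v2")
  expect_identical(v1$phenotype, "HFrEF")
  expect_identical(v2$phenotype, "HFpEF")
})

test_that("discordant same-day values classify as unspecified", {
  evidence <- mk_items(
    mk_item(days_ago = 50, values = 30, tier = "high"),
    mk_item(days_ago = 50, values = 55, tier = "high",
            provenance = "cart", modality = "TTE"))
  res <- phenotype_patient(evidence, mk_dx(code = "I50.9"), CFG, "v2")
  expect_identical(res$phenotype, "unspecified")
})

test_that("legacy ICD-only fallback maps systolic and diastolic codes", {
  cases <- list(list(code = "I50.22", want = "HFrEF"),
                list(code = "I50.32", want = "HFpEF"),
                list(code = "428.21", want = "HFrEF",
                     code_system = "ICD9"),
                list(code = "I50.9", want = "unspecified"))
  for (case in cases) {
    res <- phenotype_patient(
      no_evidence(),
      mk_dx(code = case$code,
            code_system = case$code_system %||% "ICD10"),
      CFG, "v1")
    expect_identical(res$phenotype, case$want, info = case$code)
  }
  # v2 has no ICD fallback: no evidence means unspecified
  res <- phenotype_patient(no_evidence(), mk_dx(code = "I50.22"), CFG,
                           "v2")
  expect_identical(res$phenotype, "unspecified")
})

test_that("every roster patient maps to exactly one outcome", {
  sim <- simulate_cohort(sim_preset("paper_like", n_patients = 120,
                                    seed = 77))
  cfg <- classification_config(as_of_date = sim$params$as_of_date)
  evidence <- build_evidence(sim$cohort)
  for (version in c("v1", "v2")) {
    res <- phenotype_cohort(sim$cohort, cfg, version, evidence)
    expect_setequal(res$patient_id, sim$cohort$roster$patient_id)
    expect_equal(anyDuplicated(res$patient_id), 0)
    outcome <- ifelse(res$included, res$phenotype, "not_included")
    expect_true(all(outcome %in% c("not_included", "HFrEF", "HFmrEF",
                                   "HFpEF", "unspecified")))
    if (version == "v1") {
      expect_false(any(outcome == "HFmrEF"))
    }
  }
})

test_that("v1 and v2 agree on a lone recent high-quality measurement", {
  dx <- mk_dx(code = "I50.9")
  for (value in c(25, 40, 50, 65)) {
    evidence <- mk_item(days_ago = 90, values = value)
    v1 <- phenotype_patient(evidence, dx, CFG, "v1")
    v2 <- phenotype_patient(evidence, dx, CFG, "v2")
    expect_identical(v1$phenotype, v2$phenotype, info = value)
  }
})
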
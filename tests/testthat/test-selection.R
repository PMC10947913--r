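test_that("multi-value resolution follows the spread and plausibility rules", {
  expect_equal(resolve_multi_value(c(55, 60), CFG), 57.5)
  expect_equal(resolve_multi_value(c(20, 35), CFG), 35)
  expect_identical(resolve_multi_value(c(80, 60), CFG),
                   "unspecified_implausible")
  expect_equal(resolve_multi_value(c(40, 40), CFG), 40)
  # three or more values: "high and low" read as max and min
  expect_equal(resolve_multi_value(c(50, 55, 58), CFG), 54)
  expect_equal(resolve_multi_value(c(20, 28, 35), CFG), 35)
  expect_error(resolve_multi_value(42, CFG), "at least 2")
})

test_that("multi-value resolution is symmetric in argument order", {
  set.seed(17)
  for (rep in 1:50) {
    values <- sample(5:95, sample(2:4, 1), replace = TRUE)
    expect_identical(resolve_multi_value(values, CFG),
                     resolve_multi_value(rev(values), CFG))
  }
})

test_that("a high-quality study within a year pre-empts newer lesser evidence", {
  evidence <- mk_items(
    mk_item(days_ago = 182, values = 30, tier = "high"),
    mk_item(days_ago = 30, values = 55, tier = "medium",
            provenance = "nlp_note", modality = NA))
  sel <- select_effective_lvef(evidence, CFG)
  expect_identical(sel$verdict, "value")
  expect_equal(sel$effective_lvef, 30)
  expect_match(sel$rule_fired, "priority_window")
})

test_that("without a recent high-quality study the most recent evidence wins", {
  sel <- select_effective_lvef(
    mk_item(days_ago = 730, values = 62, tier = "high"), CFG)
  expect_equal(sel$effective_lvef, 62)
  expect_match(sel$rule_fired, "most_recent")
  # high tier beats medium on a shared most-recent date
  evidence <- mk_items(
    mk_item(days_ago = 600, values = 30, tier = "high"),
    mk_item(days_ago = 600, values = c(50, 55), tier = "medium",
            provenance = "nlp_echo"))
  expect_equal(select_effective_lvef(evidence, CFG)$effective_lvef, 30)
})

test_that("same-date single-value studies in opposite classes conflict", {
  evidence <- mk_items(
    mk_item(days_ago = 100, values = 30, tier = "high"),
    mk_item(days_ago = 100, values = 55, tier = "high",
            provenance = "cart", modality = "TTE"))
  expect_identical(select_effective_lvef(evidence, CFG)$verdict,
                   "unspecified_conflict")
  # adjacent classes (HFrEF vs HFmrEF) are not a conflict: values pool
  evidence <- mk_items(
    mk_item(days_ago = 100, values = 38, tier = "high"),
    mk_item(days_ago = 100, values = 45, tier = "high",
            provenance = "cart", modality = "TTE"))
  sel <- select_effective_lvef(evidence, CFG)
  expect_identical(sel$verdict, "value")
  expect_equal(sel$effective_lvef, 41.5)
})

test_that("evidence outside the lookback window leaves the patient without data", {
  sel <- select_effective_lvef(
    mk_item(days_ago = 4 * 365, values = 35), CFG)
  expect_identical(sel$verdict, "unspecified_no_data")
  expect_identical(select_effective_lvef(no_evidence(), CFG)$verdict,
                   "unspecified_no_data")
})

test_that("window boundaries are calendar anniversaries, inclusive at the old end", {
  boundary <- lubridate::add_with_rollback(AS_OF, -lubridate::years(3))
  on_boundary <- mk_item(days_ago = as.integer(AS_OF - boundary),
                         values = 33)
  expect_identical(select_effective_lvef(on_boundary, CFG)$verdict,
                   "value")
  one_day_older <- mk_item(days_ago = as.integer(AS_OF - boundary) + 1L,
                           values = 33)
  expect_identical(select_effective_lvef(one_day_older, CFG)$verdict,
                   "unspecified_no_data")
})

test_that("the legacy mode takes the lowest value from any source", {
  evidence <- mk_items(
    mk_item(days_ago = 30, values = 55, tier = "high"),
    mk_item(days_ago = 400, values = 38, tier = "excluded",
            provenance = "nlp_radiology", modality = "other"))
  sel <- select_effective_lvef_v1(evidence, CFG)
  expect_equal(sel$effective_lvef, 38)
  expect_equal(select_effective_lvef_v1(
    mk_item(values = 60), CFG)$effective_lvef, 60)
  expect_identical(select_effective_lvef_v1(no_evidence(), CFG)$verdict,
                   "unspecified_no_data")
})

test_that("adding evidence never raises the legacy effective LVEF", {
  set.seed(23)
  for (rep in 1:30) {
    evidence <- random_evidence(sample(1:5, 1))
    base <- select_effective_lvef_v1(evidence, CFG)
    more <- dplyr::bind_rows(evidence, random_evidence(1))
    extended <- select_effective_lvef_v1(more, CFG)
    if (base$verdict == "value" && extended$verdict == "value") {
      expect_lte(extended$effective_lvef, base$effective_lvef)
    }
  }
})

test_that("both selection modes agree with brute-force enumeration", {
  set.seed(101)
  for (rep in 1:200) {
    expect_selection_matches_oracle(random_evidence(sample(1:6, 1)), CFG)
  }
})
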
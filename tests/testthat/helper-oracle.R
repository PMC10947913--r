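# independent brute-force enumerations of the selection cascades; written
# as plain loops so they stay a separate code path from the package

oracle_window <- function(date, as_of, years) {
  start <- lubridate::add_with_rollback(as_of, -lubridate::years(years))
  date >= start & date <= as_of
}

oracle_select_v2 <- function(evidence, cfg) {
  kept <- list()
  for (i in seq_len(nrow(evidence))) {
    row <- evidence[i, ]
    if (row$tier == "excluded") next
    if (!oracle_window(row$event_date, cfg$as_of_date,
                       cfg$lookback_years)) next
    kept[[length(kept) + 1]] <- row
  }
  if (length(kept) == 0) return(list(verdict = "unspecified_no_data"))
  high_dates <- as.Date(character())
  for (row in kept) {
    if (row$tier == "high" &&
        oracle_window(row$event_date, cfg$as_of_date,
                      cfg$high_quality_priority_years)) {
      high_dates <- c(high_dates, row$event_date)
    }
  }
  if (length(high_dates) > 0) {
    target <- max(high_dates)
    cand <- Filter(function(r) r$tier == "high" &&
                     r$event_date == target, kept)
  } else {
    target <- max(do.call(c, lapply(kept, function(r) r$event_date)))
    cand <- Filter(function(r) r$event_date == target, kept)
    if (any(vapply(cand, function(r) r$tier == "high", logical(1)))) {
      cand <- Filter(function(r) r$tier == "high", cand)
    }
  }
  singles <- unlist(lapply(cand, function(r)
    if (r$n_values == 1) r$values[[1]] else NULL))
  if (!is.null(singles) && length(singles) >= 2 &&
      any(singles <= cfg$hfref_max) &&
      any(singles >= cfg$hfmref_max + 1)) {
    return(list(verdict = "unspecified_conflict"))
  }
  pooled <- unlist(lapply(cand, function(r) r$values[[1]]))
  if (length(pooled) == 1) {
    return(list(verdict = "value", lvef = pooled))
  }
  if (any(pooled > cfg$implausible_value_threshold)) {
    return(list(verdict = "unspecified_implausible"))
  }
  if (max(pooled) - min(pooled) <= cfg$multi_value_avg_threshold) {
    list(verdict = "value", lvef = (max(pooled) + min(pooled)) / 2)
  } else {
    list(verdict = "value", lvef = max(pooled))
  }
}

oracle_select_v1 <- function(evidence, cfg) {
  values <- numeric(0)
  for (i in seq_len(nrow(evidence))) {
    row <- evidence[i, ]
    if (oracle_window(row$event_date, cfg$as_of_date,
                      cfg$lookback_years)) {
      values <- c(values, row$values[[1]])
    }
  }
  if (length(values) == 0) return(list(verdict = "unspecified_no_data"))
  list(verdict = "value", lvef = min(values))
}

expect_selection_matches_oracle <- function(evidence, cfg) {
  got2 <- select_effective_lvef(evidence, cfg)
  want2 <- oracle_select_v2(evidence, cfg)
  expect_identical(got2$verdict, want2$verdict)
  if (want2$verdict == "value") {
    expect_equal(got2$effective_lvef, unname(want2$lvef))
  }
  got1 <- select_effective_lvef_v1(evidence, cfg)
  want1 <- oracle_select_v1(evidence, cfg)
  expect_identical(got1$verdict, want1$verdict)
  if (want1$verdict == "value") {
    expect_equal(got1$effective_lvef, unname(want1$lvef))
  }
}

# reference confusion metrics via caret, an independent implementation
reference_confusion <- function(gold, predicted, positive_class) {
  lv <- c(positive_class, ".rest")
  g <- factor(ifelse(gold == positive_class, positive_class, ".rest"),
              levels = lv)
  p <- factor(ifelse(predicted == positive_class, positive_class,
                     ".rest"), levels = lv)
  cm <- caret::confusionMatrix(p, g, positive = positive_class)
  list(sensitivity = 100 * unname(cm$byClass["Sensitivity"]),
       specificity = 100 * unname(cm$byClass["Specificity"]),
       accuracy = 100 * unname(cm$overall["Accuracy"]),
       ppv = 100 * unname(cm$byClass["Pos Pred Value"]),
       npv = 100 * unname(cm$byClass["Neg Pred Value"]))
}
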
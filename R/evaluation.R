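#' One-vs-rest confusion summary for one phenotype class
#'
#' Counts true/false positives/negatives for `positive_class` against
#' all other labels and derives the standard diagnostic-accuracy
#' metrics, as percentages: sensitivity `100*TP/(TP+FN)`, specificity
#' `100*TN/(TN+FP)`, accuracy `100*(TP+TN)/N` (the ratio of true
#' results to the total population), PPV `100*TP/(TP+FP)`, NPV
#' `100*TN/(TN+FN)`. A zero denominator yields `NA` for that metric.
#'
#' @param gold named character vector (or tibble with `patient_id`,
#'   `label`) of gold-standard labels.
#' @param predicted same structure; must cover exactly the same patient
#'   set.
#' @param positive_class the class treated as positive.
#' @return A one-row tibble: `class`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv`.
#' @export
confusion <- function(gold, predicted, positive_class) {
  gold <- as_label_vector(gold)
  predicted <- as_label_vector(predicted)
  if (!setequal(names(gold), names(predicted)) ||
      length(gold) != length(predicted)) {
    abort("gold and predicted labels must cover the same patient set")
  }
  predicted <- predicted[names(gold)]
  gp <- gold == positive_class
  pp <- predicted == positive_class
  tp <- sum(gp & pp); fp <- sum(!gp & pp)
  tn <- sum(!gp & !pp); fn <- sum(gp & !pp)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    class = positive_class, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    accuracy = pct(tp + tn, tp + fp + tn + fn),
    ppv = pct(tp, tp + fp),
    npv = pct(tn, tn + fn))
}

as_label_vector <- function(x) {
  if (is.data.frame(x)) {
    out <- setNames(as.character(x$label), x$patient_id)
  } else {
    out <- x
  }
  if (is.null(names(out)) || any(names(out) == "")) {
    abort("labels must be named by patient_id")
  }
  out
}

#' Confusion summaries for every phenotype class
#'
#' @inheritParams confusion
#' @param classes classes to evaluate (default: phenotype classes
#'   present in the gold labels).
#' @return A tibble with one [confusion()] row per class.
#' @export
confusion_by_class <- function(gold, predicted, classes = NULL) {
  gold <- as_label_vector(gold)
  predicted <- as_label_vector(predicted)
  classes <- classes %||% sort(unique(gold))
  dplyr::bind_rows(lapply(classes, function(cl) {
    confusion(gold, predicted, cl)
  }))
}

#' Compare both algorithm versions against gold labels
#'
#' Runs each version's predictions against the gold phenotypes,
#' one-vs-rest per class, and reports the per-metric deltas (v2 minus
#' v1). By default only patients the algorithm classified (included,
#' non-unspecified) enter a version's evaluation population; set
#' `population = "all_included"` to keep unspecified predictions as
#' all-negative labels instead.
#'
#' @param phenotypes_v1,phenotypes_v2 tibbles from [phenotype_cohort()].
#' @param gold tibble with `patient_id`, `true_phenotype`.
#' @param population `"classified_only"` (default) or `"all_included"`.
#' @return A list: `v1`, `v2` (per-class summaries with an `n_evaluated`
#'   column) and `delta` (per-class metric differences).
#' @export
compare_versions <- function(phenotypes_v1, phenotypes_v2, gold,
                             population = c("classified_only",
                                            "all_included")) {
  population <- match.arg(population)
  gold_vec <- setNames(gold$true_phenotype, gold$patient_id)
  classes <- sort(unique(gold$true_phenotype))
  eval_one <- function(phenotypes) {
    keep <- phenotypes$included
    if (population == "classified_only") {
      keep <- keep & phenotypes$phenotype != "unspecified"
    }
    pred <- setNames(phenotypes$phenotype[keep],
                     phenotypes$patient_id[keep])
    pred_gold <- gold_vec[names(pred)]
    if (anyNA(pred_gold)) {
      abort("gold labels missing for some evaluated patients")
    }
    out <- confusion_by_class(pred_gold, pred, classes)
    out$n_evaluated <- length(pred)
    out
  }
  v1 <- eval_one(phenotypes_v1)
  v2 <- eval_one(phenotypes_v2)
  metrics <- c("sensitivity", "specificity", "accuracy", "ppv", "npv")
  delta <- v2[c("class", metrics)]
  for (m in metrics) delta[[m]] <- v2[[m]] - v1[[m]]
  list(v1 = v1, v2 = v2, delta = delta)
}

#' Write evaluation summaries as CSV
#'
#' @param comparison list from [compare_versions()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_evaluation <- function(comparison, path) {
  v1 <- dplyr::mutate(comparison$v1, version = "v1", .before = 1)
  v2 <- dplyr::mutate(comparison$v2, version = "v2", .before = 1)
  readr::write_csv(dplyr::bind_rows(v1, v2), path, na = "")
  invisible(path)
}
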
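#' Confusion-matrix summary with predictive values
#'
#' Derives accuracy, sensitivity, specificity, positive predictive value
#' (PPV) and negative predictive value (NPV) from raw confusion counts, with
#' predicted/observed response (`R`) as the positive class. A metric whose
#' denominator is zero is reported as `NA` (absent), never coerced to 0.
#'
#' @param tp,tn,fp,fn Non-negative counts (sum > 0).
#' @return A `confusion_summary` object.
#' @examples
#' glance(confusion_metrics(17, 2, 3, 1))
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "chemoresponse_input_error")
  }
  if (sum(counts) == 0) {
    abort("Confusion counts sum to zero; nothing to summarise.",
          class = "chemoresponse_input_error")
  }
  structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn,
         accuracy = safe_ratio(tp + tn, tp + tn + fp + fn),
         sensitivity = safe_ratio(tp, tp + fn),
         specificity = safe_ratio(tn, tn + fp),
         ppv = safe_ratio(tp, tp + fp),
         npv = safe_ratio(tn, tn + fn)),
    class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> TP %d | TN %d | FP %d | FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("  accuracy %s, sensitivity %s, specificity %s, PPV %s, NPV %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' @describeIn confusion_metrics Metrics in long form (`metric`, `value`).
#' @param x,... A `confusion_summary` and ignored arguments.
#' @method tidy confusion_summary
#' @export
tidy.confusion_summary <- function(x, ...) {
  tibble(metric = c("accuracy", "sensitivity", "specificity", "ppv", "npv"),
         value = c(x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv))
}

#' @describeIn confusion_metrics Counts and metrics as a one-row tibble.
#' @method glance confusion_summary
#' @export
glance.confusion_summary <- function(x, ...) {
  tibble(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn,
         accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, ppv = x$ppv, npv = x$npv)
}

#' Leave-one-out cross-validation of the response classifier
#'
#' Each sample in turn is held out; the feature scaler and the classifier
#' are refit on the remaining samples and the held-out sample is scored.
#' Confusion counts accumulate over folds (responder `R` positive).
#'
#' In the default `"fixed"` mode the feature set is decided before entry
#' (e.g. by [rfe_select()] on a separate split) and only the scaler and
#' hyperplane are refit per fold; this evaluates a chosen gene signature. In
#' `"nested"` mode the full elimination is rerun inside every fold on an
#' inner stratified split, which is slower but free of selection bias.
#'
#' @param expr Raw (unscaled) expression matrix, features x samples.
#' @param labels Named `"R"`/`"NR"` vector covering the samples.
#' @param features Feature ids to use (`"fixed"` mode); default all rows.
#' @param cost Soft-margin penalty.
#' @param mode `"fixed"` or `"nested"` (see Details).
#' @param log2_transform Passed to [fit_scaler()] in every fold.
#' @param block,floor,train_fraction Nested-mode elimination parameters.
#' @param seed Base seed for nested-mode inner splits (fold index is added).
#'
#' @return A `confusion_summary` whose `predictions` attribute holds the
#'   per-fold tibble (`sample_id`, `score`, `call`, `observed`).
#' @export
loocv <- function(expr, labels, features = NULL, cost = 1,
                  mode = c("fixed", "nested"), log2_transform = TRUE,
                  block = 100, floor = 100, train_fraction = 0.75, seed = 1) {
  mode <- match.arg(mode)
  assert_expression_matrix(expr)
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) {
    abort("`labels` must cover every sample by name.",
          class = "chemoresponse_input_error")
  }
  if (any(table(labels) < 2)) {
    abort("LOOCV requires at least 2 samples per class.",
          class = "chemoresponse_input_error")
  }
  if (is.null(features)) features <- rownames(expr)
  missing <- setdiff(features, rownames(expr))
  if (length(missing)) {
    abort(sprintf("`features` not present in `expr`: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "chemoresponse_feature_mismatch_error")
  }
  n <- ncol(expr)
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    held_id <- colnames(expr)[i]
    tr <- expr[, -i, drop = FALSE]
    tr_labels <- labels[colnames(tr)]
    if (length(unique(tr_labels)) < 2) {
      abort(sprintf("Fold %d (holding out %s) leaves a single-class training set.",
                    i, held_id),
            class = "chemoresponse_fold_degeneracy_error")
    }
    if (mode == "fixed") {
      scaler <- fit_scaler(tr[features, , drop = FALSE],
                           log2_transform = log2_transform)
      model <- fit_linear_svm(apply_scaler(scaler, tr), tr_labels, cost = cost)
    } else {
      scaler <- fit_scaler(tr, log2_transform = log2_transform)
      tr_scaled <- apply_scaler(scaler, tr)
      inner <- split_train_test(tr_labels, train_fraction = train_fraction,
                                seed = seed + i)
      rfe <- rfe_select(tr_scaled[, inner$train, drop = FALSE],
                        tr_labels[inner$train],
                        tr_scaled[, inner$test, drop = FALSE],
                        tr_labels[inner$test],
                        cost = cost, block = block, floor = floor)
      scaler <- fit_scaler(tr[rfe$selected_features, , drop = FALSE],
                           log2_transform = log2_transform)
      model <- fit_linear_svm(apply_scaler(scaler, tr), tr_labels, cost = cost)
    }
    held <- apply_scaler(scaler, expr[, i, drop = FALSE])
    preds[[i]] <- prediction_score(model, held)
  }
  preds <- dplyr::bind_rows(preds) %>%
    mutate(observed = unname(labels[.data$sample_id])) %>%
    select("sample_id", "score", "call", "observed")
  out <- confusion_metrics(
    tp = sum(preds$call == "R" & preds$observed == "R"),
    tn = sum(preds$call == "NR" & preds$observed == "NR"),
    fp = sum(preds$call == "R" & preds$observed == "NR"),
    fn = sum(preds$call == "NR" & preds$observed == "R"))
  attr(out, "predictions") <- preds
  attr(out, "mode") <- mode
  out
}

#' Classify treatment response from a CA-125 trajectory
#'
#' A patient is called a responder when the serum CA-125 level normalizes
#' after treatment: under the default `"any"` rule, when the minimum
#' post-treatment value falls strictly below the threshold (35 U/mL by
#' default); under the `"final"` rule, when the last measurement does. A
#' value exactly at the threshold is not a response.
#'
#' @param series A `ca125_series` from [generate_ca125_series()], or a tibble
#'   with `time`, `ca125` and `phase` (`"pre"`/`"post"`) columns.
#' @param threshold Normality threshold (U/mL); defaults to the series
#'   attribute, else 35.
#' @param rule `"any"` (default) or `"final"`.
#'
#' @return `"R"` or `"NR"`.
#' @export
ca125_response <- function(series, threshold = NULL, rule = c("any", "final")) {
  rule <- match.arg(rule)
  if (is.null(threshold)) {
    threshold <- attr(series, "threshold") %||% 35
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("`threshold` must be a positive CA-125 level (U/mL).",
          class = "chemoresponse_parameter_error")
  }
  if (!all(c("ca125", "phase") %in% names(series))) {
    abort("`series` must have `ca125` and `phase` columns.",
          class = "chemoresponse_input_error")
  }
  post <- series$ca125[series$phase == "post"]
  if (!length(post)) {
    abort("`series` has no post-treatment measurements.",
          class = "chemoresponse_input_error")
  }
  ref <- if (rule == "any") min(post) else post[length(post)]
  if (ref < threshold) "R" else "NR"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a combination-therapy prediction against the observed outcome
#'
#' A patient on combination therapy counts as predicted-responsive when at
#' least one administered drug is called `R`. Crossing that with the
#' observed response gives the outcome: predicted-responsive and observed
#' `R` is a true positive (TP), predicted-responsive and observed `NR` a
#' false positive (FP); no predicted response with observed `NR` is a true
#' negative (TN) and with observed `R` a false negative (FN).
#'
#' @param administered Character vector of administered drug names.
#' @param calls Named `"R"`/`"NR"` vector of per-drug predicted calls; must
#'   cover every administered drug.
#' @param observed Observed response, `"R"` or `"NR"`.
#' @param patient_id Optional identifier carried into the result.
#'
#' @return One-row tibble: `patient_id`, `drugs` (semicolon-joined),
#'   `predicted_any`, `observed`, `outcome`.
#' @examples
#' combination_call(c("carboplatin", "paclitaxel"),
#'                  c(carboplatin = "NR", paclitaxel = "NR"), "R")  # FN
#' @export
combination_call <- function(administered, calls, observed,
                             patient_id = NA_character_) {
  if (!length(administered)) {
    abort("`administered` must list at least one drug.",
          class = "chemoresponse_input_error")
  }
  uncovered <- setdiff(administered, names(calls))
  if (length(uncovered)) {
    abort(sprintf("No predicted call for administered drug(s): %s",
                  paste(uncovered, collapse = ", ")),
          class = "chemoresponse_coverage_error")
  }
  if (!observed %in% c("R", "NR")) {
    abort("`observed` must be \"R\" or \"NR\".",
          class = "chemoresponse_input_error")
  }
  predicted_any <- any(calls[administered] == "R")
  outcome <- if (predicted_any) {
    if (observed == "R") "TP" else "FP"
  } else {
    if (observed == "NR") "TN" else "FN"
  }
  tibble(patient_id = patient_id,
         drugs = paste(administered, collapse = ";"),
         predicted_any = predicted_any, observed = observed,
         outcome = outcome)
}

#' Assess every patient of a combination-therapy cohort
#'
#' Applies [combination_call()] row-wise to a cohort table in the package's
#' wide layout: `patient_id`, `drugs` (semicolon-separated administered
#' drugs), `observed`, plus one `"R"`/`"NR"` call column per drug (as
#' returned by [ovarian_predictions()]).
#'
#' @param data Wide cohort tibble (see Details).
#' @return Tibble of per-patient assessments, one row per patient.
#' @export
assess_combinations <- function(data) {
  required <- c("patient_id", "drugs", "observed")
  if (!all(required %in% names(data))) {
    abort(sprintf("`data` must have columns %s plus per-drug call columns.",
                  paste(required, collapse = ", ")),
          class = "chemoresponse_input_error")
  }
  drug_cols <- setdiff(names(data), required)
  purrr::pmap(data, function(patient_id, drugs, observed, ...) {
    calls <- unlist(list(...))
    combination_call(strsplit(drugs, ";", fixed = TRUE)[[1]],
                     calls, observed, patient_id = patient_id)
  }) %>%
    dplyr::bind_rows()
}

#' Aggregate combination-therapy assessments into a confusion summary
#'
#' @param assessments Tibble of per-patient assessments from
#'   [combination_call()] / [assess_combinations()].
#' @return A `confusion_summary`; outcome counts partition the patients.
#' @export
aggregate_combination <- function(assessments) {
  if (!nrow(assessments) || !"outcome" %in% names(assessments)) {
    abort("`assessments` must be a non-empty tibble with an `outcome` column.",
          class = "chemoresponse_input_error")
  }
  confusion_metrics(tp = sum(assessments$outcome == "TP"),
                    tn = sum(assessments$outcome == "TN"),
                    fp = sum(assessments$outcome == "FP"),
                    fn = sum(assessments$outcome == "FN"))
}

#' Count patients predicted to respond to a drug
#'
#' @param calls Wide tibble of per-patient calls with one `"R"`/`"NR"`
#'   column per drug (e.g. [ovarian_predictions()]).
#' @param drug Drug column to tally.
#' @return Integer count of patients called `R` for that drug.
#' @export
predicted_response_counts <- function(calls, drug) {
  if (!drug %in% names(calls)) {
    abort(sprintf("Drug %s has no call column in `calls`.", shQuote(drug)),
          class = "chemoresponse_coverage_error")
  }
  sum(calls[[drug]] == "R")
}

#' @describeIn predicted_response_counts Tally every drug column at once.
#' @param drugs Character vector of drug columns; defaults to every column
#'   other than `patient_id`, `drugs`, `observed`.
#' @export
predicted_response_summary <- function(calls, drugs = NULL) {
  if (is.null(drugs)) {
    drugs <- setdiff(names(calls), c("patient_id", "drugs", "observed"))
  }
  tibble(drug = drugs,
         n_predicted_r = vapply(unname(drugs), function(d)
           predicted_response_counts(calls, d), integer(1), USE.NAMES = FALSE),
         n_patients = nrow(calls))
}

#' Percentile placement of a prediction score within a cohort
#'
#' Places one patient's drug score within the distribution of previously
#' scored patients, as a midrank percentile: with
#' \eqn{r = \#\{s < x\} + (\#\{s = x\} + 1)/2}, the percentile is
#' \eqn{100 (r - 1) / (n - 1)}. The cohort minimum maps to 0, the maximum to
#' 100, and the median of an odd-sized distinct cohort to 50.
#'
#' @param score Numeric score of the new patient.
#' @param cohort_scores Cohort score distribution (length >= 2).
#' @return Percentile in \[0, 100\].
#' @export
score_placement <- function(score, cohort_scores) {
  if (!length(cohort_scores)) {
    abort("`cohort_scores` must be non-empty.",
          class = "chemoresponse_input_error")
  }
  n <- length(cohort_scores)
  if (n == 1L) return(50)
  r <- sum(cohort_scores < score) + (sum(cohort_scores == score) + 1) / 2
  100 * (r - 1) / (n - 1)
}

#' Rank candidate second-line drugs for one patient
#'
#' Drugs the patient has not already received and whose prediction score is
#' strictly positive (predicted sensitive), ordered by descending score —
#' the candidate list a clinician would consider after a failed first-line
#' therapy.
#'
#' @param drug_scores Named numeric vector of per-drug prediction scores.
#' @param administered Drugs already administered (excluded).
#' @return Tibble (`drug`, `score`) sorted by descending score; zero rows
#'   when no candidate has a positive score.
#' @examples
#' recommend_second_line(c(gemcitabine = 1.2, topotecan = 0.3,
#'                         gefitinib = -0.5),
#'                       administered = c("carboplatin", "paclitaxel"))
#' @export
recommend_second_line <- function(drug_scores, administered = character(0)) {
  if (is.null(names(drug_scores))) {
    abort("`drug_scores` must be named by drug.",
          class = "chemoresponse_input_error")
  }
  keep <- !(names(drug_scores) %in% administered) & drug_scores > 0
  out <- tibble(drug = names(drug_scores)[keep],
                score = unname(drug_scores[keep]))
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' Bundled ovarian cancer combination-therapy cohort
#'
#' Predicted and observed responses of 23 ovarian cancer patients treated
#' with one or more of eight chemotherapeutic drugs (carboplatin,
#' paclitaxel, cisplatin, gemcitabine, docetaxel, doxorubicin, gefitinib,
#' topotecan), transcribed from a published clinical evaluation of the
#' expression-based response predictor. `drugs` lists the administered
#' drugs (semicolon-separated); `observed` is the CA-125-derived response;
#' the remaining columns are per-drug predicted calls.
#'
#' @return Wide tibble with 23 rows, ready for [assess_combinations()] and
#'   [predicted_response_summary()].
#' @examples
#' ovarian_predictions() |> assess_combinations() |> aggregate_combination()
#' @export
ovarian_predictions <- function() {
  path <- system.file("extdata", "ovarian_predictions.csv",
                      package = "chemoresponse", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
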
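test_that("confusion metrics match their defining ratios", {
  cm <- confusion_metrics(17, 2, 3, 1)
  expect_equal(cm$ppv, 0.85)
  expect_equal(round(cm$sensitivity, 3), 0.944)
  expect_equal(round(cm$npv, 3), 0.667)
  expect_equal(cm$specificity, 0.40)
  expect_equal(round(cm$accuracy, 3), 0.826)

  # degenerate denominators are absent, never zero
  d <- confusion_metrics(5, 0, 0, 0)
  expect_equal(d$accuracy, 1)
  expect_equal(d$ppv, 1)
  expect_true(is.na(d$specificity))
  expect_true(is.na(d$npv))

  expect_error(confusion_metrics(-1, 0, 0, 2),
               class = "chemoresponse_input_error")
  expect_error(confusion_metrics(0, 0, 0, 0),
               class = "chemoresponse_input_error")

  # property: 1,000 random count tuples against the direct formulas
  withr::with_seed(31, {
    for (i in 1:1000) {
      k <- rpois(4, 5)
      if (sum(k) == 0) k[1] <- 1L
      cm <- confusion_metrics(k[1], k[2], k[3], k[4])
      expect_equal(cm$accuracy, (k[1] + k[2]) / sum(k))
      expect_equal(cm$sensitivity,
                   if (k[1] + k[4] > 0) k[1] / (k[1] + k[4]) else NA_real_)
      expect_equal(cm$specificity,
                   if (k[2] + k[3] > 0) k[2] / (k[2] + k[3]) else NA_real_)
      expect_equal(cm$ppv,
                   if (k[1] + k[3] > 0) k[1] / (k[1] + k[3]) else NA_real_)
      expect_equal(cm$npv,
                   if (k[2] + k[4] > 0) k[2] / (k[2] + k[4]) else NA_real_)
    }
  })
})

test_that("LOOCV is perfect on separated clusters and sums to n", {
  co <- generate_cohort(cohort_config(n_patients = 16, n_genes = 10,
                                      n_informative = 4, effect_size = 10,
                                      responder_fraction = 0.5,
                                      zero_inflation = 0, seed = 13))
  cm <- loocv(co$expression, co$truth_labels)
  expect_equal(cm$accuracy, 1)
  expect_identical(cm$tp + cm$tn + cm$fp + cm$fn, 16L)
  preds <- attr(cm, "predictions")
  expect_identical(nrow(preds), 16L)
  expect_setequal(preds$sample_id, colnames(co$expression))
})

test_that("LOOCV equals a hand-rolled per-fold loop on a 12-sample toy", {
  co <- generate_cohort(cohort_config(n_patients = 12, n_genes = 8,
                                      n_informative = 2, effect_size = 1.5,
                                      responder_fraction = 0.5,
                                      zero_inflation = 0, seed = 21))
  expr <- co$expression
  labels <- co$truth_labels
  cm <- loocv(expr, labels)

  # independent re-implementation of the fold loop
  calls <- scores <- setNames(vector("list", ncol(expr)), colnames(expr))
  for (id in colnames(expr)) {
    rest <- setdiff(colnames(expr), id)
    sc <- fit_scaler(expr[, rest, drop = FALSE])
    m <- fit_linear_svm(apply_scaler(sc, expr[, rest, drop = FALSE]),
                        labels[rest])
    p <- prediction_score(m, apply_scaler(sc, expr[, id, drop = FALSE]))
    calls[[id]] <- p$call
    scores[[id]] <- p$score
  }
  calls <- unlist(calls)
  scores <- unlist(scores)
  preds <- attr(cm, "predictions")
  expect_identical(preds$call, unname(calls[preds$sample_id]))
  expect_equal(preds$score, unname(scores[preds$sample_id]))
  expect_identical(cm$tp, sum(calls == "R" & labels == "R"))
  expect_identical(cm$fn, sum(calls == "NR" & labels == "R"))
})

test_that("LOOCV rejects cohorts that cannot stratify folds", {
  co <- generate_cohort(cohort_config(n_patients = 8, n_genes = 6,
                                      n_informative = 0,
                                      responder_fraction = 0.5,
                                      zero_inflation = 0, seed = 2))
  labels <- co$truth_labels
  labels[labels == "R"] <- "NR"
  labels[1] <- "R"
  expect_error(loocv(co$expression, labels),
               class = "chemoresponse_input_error")
})

test_that("nested LOOCV reruns selection inside folds", {
  co <- generate_cohort(cohort_config(n_patients = 16, n_genes = 12,
                                      n_informative = 3, effect_size = 5,
                                      responder_fraction = 0.5,
                                      zero_inflation = 0, seed = 17))
  cm <- loocv(co$expression, co$truth_labels, mode = "nested",
              block = 5, floor = 5, seed = 1)
  expect_identical(attr(cm, "mode"), "nested")
  expect_identical(cm$tp + cm$tn + cm$fp + cm$fn, 16L)
  expect_gte(cm$accuracy, 0.75)   # strong signal survives nesting
})

test_that("CA-125 trajectories classify by the strict threshold rule", {
  series <- function(post) {
    tibble::tibble(time = seq_along(post) * 30,
                   ca125 = post, phase = "post")
  }
  expect_identical(ca125_response(series(c(120, 60, 20))), "R")
  expect_identical(ca125_response(series(c(400, 90, 36))), "NR")
  expect_identical(ca125_response(series(c(100, 35))), "NR")  # 35 is not <35

  # "final" rule looks only at the last measurement
  dipped <- series(c(20, 80, 90))
  expect_identical(ca125_response(dipped, rule = "any"), "R")
  expect_identical(ca125_response(dipped, rule = "final"), "NR")

  expect_error(ca125_response(series(c(10)), threshold = -5),
               class = "chemoresponse_parameter_error")
})

test_that("combination outcomes follow the any-administered-drug rule", {
  fn <- combination_call(c("carboplatin", "paclitaxel"),
                         c(carboplatin = "NR", paclitaxel = "NR"), "R",
                         patient_id = "BJ1")
  expect_identical(fn$outcome, "FN")
  fp <- combination_call(c("carboplatin", "paclitaxel"),
                         c(carboplatin = "R", paclitaxel = "NR"), "NR",
                         patient_id = "1145")
  expect_identical(fp$outcome, "FP")
  tn <- combination_call(c("carboplatin", "paclitaxel"),
                         c(carboplatin = "NR", paclitaxel = "NR"), "NR",
                         patient_id = "286")
  expect_identical(tn$outcome, "TN")
  tp <- combination_call(c("carboplatin", "gemcitabine"),
                         c(carboplatin = "NR", gemcitabine = "R"), "R")
  expect_identical(tp$outcome, "TP")
  # calls for non-administered drugs never matter
  tp2 <- combination_call("topotecan",
                          c(topotecan = "NR", carboplatin = "R"), "NR")
  expect_identical(tp2$outcome, "TN")

  expect_error(combination_call(c("carboplatin", "docetaxel"),
                                c(carboplatin = "R"), "R"),
               "docetaxel", class = "chemoresponse_coverage_error")
})

test_that("switching one call NR to R never moves toward the negative pair", {
  withr::with_seed(44, {
    drugs <- c("a", "b", "c")
    for (i in 1:100) {
      calls <- setNames(sample(c("R", "NR"), 3, replace = TRUE), drugs)
      administered <- sample(drugs, sample(1:3, 1))
      observed <- sample(c("R", "NR"), 1)
      base <- combination_call(administered, calls, observed)$outcome
      flip <- administered[calls[administered] == "NR"]
      if (length(flip)) {
        calls2 <- calls
        calls2[flip[1]] <- "R"
        out2 <- combination_call(administered, calls2, observed)$outcome
        expect_true(out2 %in% c("TP", "FP"))
        if (base %in% c("TP", "FP")) expect_identical(out2, base)
      }
    }
  })
})

test_that("aggregation partitions patients across the four outcomes", {
  single <- aggregate_combination(
    combination_call("a", c(a = "R"), "R"))
  expect_identical(glance(single)[, c("tp", "tn", "fp", "fn")],
                   tibble::tibble(tp = 1L, tn = 0L, fp = 0L, fn = 0L))

  tab <- ovarian_predictions()
  assessments <- assess_combinations(tab)
  expect_identical(nrow(assessments), nrow(tab))
  cm <- aggregate_combination(assessments)
  expect_identical(cm$tp + cm$tn + cm$fp + cm$fn, nrow(tab))
})

test_that("per-drug tallies count positive calls", {
  tab <- tibble::tibble(patient_id = c("p1", "p2", "p3"),
                        drugs = "x", observed = "R",
                        x = c("R", "NR", "R"), y = c("NR", "NR", "NR"))
  expect_identical(predicted_response_counts(tab, "x"), 2L)
  expect_identical(predicted_response_counts(tab, "y"), 0L)
  expect_error(predicted_response_counts(tab, "z"),
               class = "chemoresponse_coverage_error")
  summ <- predicted_response_summary(tab)
  expect_identical(summ$n_predicted_r, c(2L, 0L))
})

test_that("score placement uses the midrank convention", {
  expect_equal(score_placement(5, c(1, 2, 3, 4, 5)), 100)
  expect_equal(score_placement(1, c(1, 2, 3, 4, 5)), 0)
  expect_equal(score_placement(3, c(1, 2, 3, 4, 5)), 50)
  # ties: midrank between the tied block's neighbours
  expect_equal(score_placement(2, c(1, 2, 2, 3)), 50)
  expect_error(score_placement(1, numeric(0)),
               class = "chemoresponse_input_error")
})

test_that("second-line ranking keeps positive, non-administered drugs", {
  rec <- recommend_second_line(
    c(gemcitabine = 1.2, topotecan = 0.3, gefitinib = -0.5,
      carboplatin = 2.0),
    administered = c("carboplatin", "paclitaxel"))
  expect_identical(rec$drug, c("gemcitabine", "topotecan"))
  expect_identical(rec$score, c(1.2, 0.3))
  none <- recommend_second_line(c(a = -1, b = -2))
  expect_identical(nrow(none), 0L)
})
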
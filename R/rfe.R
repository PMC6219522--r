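#' Rank features of a fitted linear model by importance
#'
#' Orders features by descending squared weight \eqn{w_f^2}, the standard
#' recursive-elimination importance criterion for a linear max-margin model
#' (the squared magnitude measures how much a feature moves the decision
#' value, independent of direction). Ties are broken by lexicographic feature
#' id, so the ranking is deterministic and invariant to input feature order.
#'
#' @param model A fitted `drug_svm`.
#' @return Character vector of feature ids, most to least important.
#' @export
rank_features <- function(model) {
  if (!inherits(model, "drug_svm")) {
    abort("`model` must be a fitted drug_svm.",
          class = "chemoresponse_input_error")
  }
  names(model$w)[order(-model$w^2, names(model$w))]
}

#' Staged elimination schedule
#'
#' Number of features removed at each elimination step: blocks of `block`
#' (default 100) lowest-ranked features are removed while more than `floor`
#' features remain — with a partial block of `remaining - floor` so the
#' schedule lands exactly on `floor` — and from there features are removed
#' one at a time down to a single feature. The removal counts always sum to
#' `n_start - 1`.
#'
#' @param n_start Number of features before elimination.
#' @param block Block size of the coarse phase (default 100).
#' @param floor Feature count at which elimination switches to one-at-a-time
#'   (default 100).
#'
#' @return Integer vector of per-step removal counts.
#' @examples
#' rfe_step_sizes(350)[1:4]  # 100 100 50 1
#' @export
rfe_step_sizes <- function(n_start, block = 100, floor = 100) {
  if (!is.numeric(n_start) || n_start < 1 || n_start != round(n_start)) {
    abort("`n_start` must be a positive integer.",
          class = "chemoresponse_parameter_error")
  }
  steps <- integer(0)
  remaining <- as.integer(n_start)
  while (remaining > floor) {
    drop <- min(block, remaining - floor)
    steps <- c(steps, as.integer(drop))
    remaining <- remaining - drop
  }
  if (remaining > 1) steps <- c(steps, rep(1L, remaining - 1L))
  steps
}

#' Recursive feature elimination with accuracy tracing
#'
#' Starting from the full feature set, repeatedly fits the linear max-margin
#' classifier on the training samples, records its accuracy on the
#' evaluation samples, and removes the lowest-ranked features according to
#' the staged schedule of [rfe_step_sizes()]. The retained model is the one
#' maximizing evaluation accuracy; among ties, the one with the fewest
#' features. The final model is refit on the selected feature set.
#'
#' Note the evaluation samples steer feature selection, exactly as the
#' procedure is defined; accuracy measured on them is therefore an
#' optimistic estimate. Use an untouched third set, or [loocv()] in nested
#' mode, for unbiased assessment.
#'
#' @param train,train_labels Scaled training matrix (features x samples) and
#'   named `"R"`/`"NR"` labels.
#' @param eval_expr,eval_labels Scaled evaluation matrix over the same
#'   feature universe, and its labels.
#' @param cost Soft-margin penalty passed to [fit_linear_svm()].
#' @param block,floor Schedule parameters of [rfe_step_sizes()].
#' @param eval_mode How the trace accuracy is measured: `"split"` (default)
#'   scores the evaluation samples with the model fit on the training
#'   samples; `"loocv"` instead records, at each step, leave-one-out
#'   accuracy over the pooled train and evaluation samples with the current
#'   feature set (hyperplane refit per fold; the feature scaling is the one
#'   the caller applied). The pooled mode has finer accuracy granularity,
#'   so ties at the minimum-feature end are rarer, at a much higher cost.
#' @param drug,label_encoding,seed Passed through to the fitted models.
#'
#' @return An `rfe_result` with elements `model` (final `drug_svm`), `trace`
#'   (tibble `n_features`, `accuracy`), `selected_n`, `selected_features`
#'   (ordered by importance in the selected model).
#' @export
rfe_select <- function(train, train_labels, eval_expr, eval_labels,
                       cost = 1, block = 100, floor = 100,
                       eval_mode = c("split", "loocv"),
                       drug = NA_character_, label_encoding = c(R = -1, NR = 1),
                       seed = NA_integer_) {
  eval_mode <- match.arg(eval_mode)
  assert_expression_matrix(train, "train")
  assert_expression_matrix(eval_expr, "eval_expr")
  if (!setequal(rownames(train), rownames(eval_expr))) {
    abort("`train` and `eval_expr` must share the same feature universe.",
          class = "chemoresponse_input_error")
  }
  eval_labels <- eval_labels[colnames(eval_expr)]
  steps <- rfe_step_sizes(nrow(train), block = block, floor = floor)
  features <- rownames(train)
  n_steps <- length(steps) + 1L
  trace_n <- integer(n_steps)
  trace_acc <- numeric(n_steps)
  feature_sets <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    model <- tryCatch(
      fit_linear_svm(train[features, , drop = FALSE], train_labels,
                     cost = cost, drug = drug,
                     label_encoding = label_encoding, seed = seed),
      error = function(e) {
        abort(sprintf("Fit failed at elimination step with %d features: %s",
                      length(features), conditionMessage(e)),
              class = "chemoresponse_rfe_error", parent = e)
      })
    ranked <- rank_features(model)
    trace_n[i] <- length(features)
    if (eval_mode == "split") {
      preds <- prediction_score(model, eval_expr[features, , drop = FALSE])
      trace_acc[i] <- mean(preds$call == eval_labels[preds$sample_id])
    } else {
      pooled <- cbind(train[features, , drop = FALSE],
                      eval_expr[features, , drop = FALSE])
      pooled_labels <- c(train_labels[colnames(train)],
                         eval_labels[colnames(eval_expr)])
      trace_acc[i] <- loo_refit_accuracy(pooled, pooled_labels, cost,
                                         label_encoding)
    }
    feature_sets[[i]] <- ranked
    if (i <= length(steps)) {
      features <- ranked[seq_len(length(ranked) - steps[i])]
    }
  }
  # best accuracy; ties resolved toward the fewest features
  best <- which(trace_acc == max(trace_acc))
  sel <- best[which.min(trace_n[best])]
  selected_features <- feature_sets[[sel]]
  final <- fit_linear_svm(train[selected_features, , drop = FALSE],
                          train_labels, cost = cost, drug = drug,
                          label_encoding = label_encoding, seed = seed)
  structure(
    list(model = final,
         trace = tibble(n_features = trace_n, accuracy = trace_acc),
         selected_n = trace_n[sel],
         selected_features = rank_features(final)),
    class = "rfe_result")
}

# Leave-one-out accuracy with per-fold hyperplane refit on already scaled
# data; used for the pooled-sample trace mode of rfe_select().
loo_refit_accuracy <- function(x, labels, cost, label_encoding) {
  calls <- character(ncol(x))
  for (i in seq_len(ncol(x))) {
    m <- fit_linear_svm(x[, -i, drop = FALSE], labels[-i], cost = cost,
                        label_encoding = label_encoding)
    calls[i] <- prediction_score(m, x[, i, drop = FALSE])$call
  }
  mean(calls == labels[colnames(x)])
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> drug = %s: %d -> %d features, eval accuracy %.3f\n",
              x$model$drug, max(x$trace$n_features), x$selected_n,
              max(x$trace$accuracy)))
  invisible(x)
}

#' @describeIn rfe_select Accuracy trace as a tibble (`n_features`,
#'   `accuracy`, `selected` flag).
#' @param x,... An `rfe_result` and ignored arguments.
#' @method tidy rfe_result
#' @export
tidy.rfe_result <- function(x, ...) {
  dplyr::mutate(x$trace, selected = .data$n_features == x$selected_n)
}

#' @describeIn rfe_select One-row summary of the elimination run.
#' @method glance rfe_result
#' @export
glance.rfe_result <- function(x, ...) {
  tibble(drug = x$model$drug, n_start = max(x$trace$n_features),
         selected_n = x$selected_n, best_accuracy = max(x$trace$accuracy),
         trace_length = nrow(x$trace))
}

#' @describeIn rfe_select Accuracy-versus-feature-count trace plot; the
#'   selected model is highlighted.
#' @param object An `rfe_result`.
#' @method autoplot rfe_result
#' @export
autoplot.rfe_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$n_features, y = .data$accuracy)) +
    geom_line(colour = "grey40") +
    geom_point(data = dplyr::filter(df, .data$selected),
               colour = "red", size = 2) +
    scale_x_reverse() +
    labs(x = "Number of features retained", y = "Evaluation accuracy",
         title = sprintf("Recursive feature elimination (%s)",
                         object$model$drug)) +
    theme_minimal()
}
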
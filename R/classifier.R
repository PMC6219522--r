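#' Binarize clinical response categories into responder / non-responder
#'
#' Collapses the four clinical response categories into the binary label the
#' classifier needs: complete or partial response become responders (`"R"`),
#' progressive or stable disease become non-responders (`"NR"`). Matching is
#' case-insensitive after trimming.
#'
#' @param category Character vector of response categories.
#' @return Character vector of `"R"` / `"NR"` labels (names preserved).
#' @examples
#' binarize_response(c("Partial Response", "Stable Disease"))
#' @export
binarize_response <- function(category) {
  accepted <- c("complete response" = "R", "partial response" = "R",
                "progressive disease" = "NR", "stable disease" = "NR")
  key <- tolower(trimws(category))
  unknown <- unique(category[!key %in% names(accepted)])
  if (length(unknown)) {
    abort(sprintf(
      "Unknown response categor%s: %s. Accepted values: %s.",
      if (length(unknown) > 1) "ies" else "y",
      paste(shQuote(unknown), collapse = ", "),
      paste(shQuote(names(accepted)), collapse = ", ")),
      class = "chemoresponse_vocabulary_error")
  }
  out <- unname(accepted[key])
  names(out) <- names(category)
  out
}

#' Stratified train / test split of a labelled cohort
#'
#' Randomly assigns `round(train_fraction * n)` samples to the training set,
#' stratified by label: each class contributes `round(train_fraction * n_c)`
#' samples, with a largest-remainder correction so the class allocations sum
#' to the overall target. The split is disjoint, exhaustive, and reproducible
#' from the seed.
#'
#' @param labels Named character vector of `"R"`/`"NR"` labels (names are
#'   sample ids).
#' @param train_fraction Fraction of samples used for training (default
#'   0.75).
#' @param seed Integer seed.
#'
#' @return List with character vectors `train` and `test` of sample ids.
#' @examples
#' labs <- setNames(rep(c("R", "NR"), c(37, 55)), sprintf("P%02d", 1:92))
#' lengths(split_train_test(labs, seed = 1))  # 69 train, 23 test
#' @export
split_train_test <- function(labels, train_fraction = 0.75, seed = 1) {
  if (is.null(names(labels)) || anyDuplicated(names(labels))) {
    abort("`labels` must be named by unique sample ids.",
          class = "chemoresponse_input_error")
  }
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.",
          class = "chemoresponse_parameter_error")
  }
  tab <- table(labels)
  if (length(tab) < 2) {
    abort("Both classes must be present to stratify the split.",
          class = "chemoresponse_stratification_error")
  }
  if (any(tab < 2)) {
    abort(sprintf("Class %s has fewer than 2 members; cannot stratify.",
                  shQuote(names(tab)[which(tab < 2)[1]])),
          class = "chemoresponse_stratification_error")
  }
  n <- length(labels)
  target <- round(train_fraction * n)
  n_c <- as.integer(tab)
  alloc <- round(train_fraction * n_c)
  alloc <- pmin(pmax(alloc, 1L), n_c - 1L)
  # largest-remainder correction toward the overall target
  resid <- train_fraction * n_c - alloc
  while (sum(alloc) < target) {
    i <- order(resid, decreasing = TRUE)[1]
    alloc[i] <- alloc[i] + 1L
    resid[i] <- resid[i] - 1
  }
  while (sum(alloc) > target) {
    i <- order(resid)[1]
    alloc[i] <- alloc[i] - 1L
    resid[i] <- resid[i] + 1
  }
  with_private_seed(seed, {
    train <- character(0)
    for (k in seq_along(tab)) {
      ids <- names(labels)[labels == names(tab)[k]]
      train <- c(train, sample(ids, alloc[k]))
    }
    train <- names(labels)[names(labels) %in% train]   # restore cohort order
    list(train = train, test = setdiff(names(labels), train))
  })
}

#' Fit the linear max-margin (soft-margin SVM) drug-response classifier
#'
#' Finds the hyperplane `w . x' + b = 0` maximizing the margin between
#' responder and non-responder training samples, with slack penalty `cost`.
#' The fitted hyperplane is oriented by the label encoding: the class encoded
#' `+1` (by default non-responders) lies on the positive side, so training
#' samples of a separable problem satisfy `c * (w . x' + b) >= 1` at large
#' `cost`. The quadratic-programming solve is delegated to libsvm via
#' \pkg{e1071}; orientation, the scoring convention and all bookkeeping are
#' handled here.
#'
#' @param train Scaled training matrix, features x samples (see
#'   [fit_scaler()]).
#' @param labels Named `"R"`/`"NR"` vector covering the training samples.
#' @param cost Soft-margin penalty C (default 1).
#' @param drug Optional drug name stored in the model.
#' @param scaler Optional `feature_scaler` stored for later prediction on raw
#'   data.
#' @param label_encoding Named numeric vector mapping each class to +1/-1;
#'   default `c(R = -1, NR = 1)`, matching the convention that the
#'   prediction score `-(w . x' + b)` is positive for predicted responders.
#' @param tolerance Solver termination tolerance (libsvm epsilon).
#' @param seed Optional integer recorded in the model metadata.
#'
#' @return A `drug_svm` model with elements `w` (named weights), `b`,
#'   `feature_ids`, `label_encoding`, `cost`, `drug`, `scaler`,
#'   `training_accuracy`.
#' @export
fit_linear_svm <- function(train, labels, cost = 1, drug = NA_character_,
                           scaler = NULL, label_encoding = c(R = -1, NR = 1),
                           tolerance = 1e-3, seed = NA_integer_) {
  assert_expression_matrix(train, "train")
  labels <- labels[colnames(train)]
  if (anyNA(labels)) {
    abort("`labels` must cover every training sample by name.",
          class = "chemoresponse_input_error")
  }
  if (!setequal(names(label_encoding), c("R", "NR")) ||
      !setequal(label_encoding, c(-1, 1))) {
    abort("`label_encoding` must map R and NR onto -1 and +1.",
          class = "chemoresponse_config_error")
  }
  if (length(unique(labels)) < 2) {
    abort("Training labels contain a single class; cannot fit a separating hyperplane.",
          class = "chemoresponse_degenerate_label_error")
  }
  fit <- e1071::svm(x = t(train), y = factor(labels, levels = c("NR", "R")),
                    kernel = "linear", cost = cost, scale = FALSE,
                    tolerance = tolerance)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  names(w) <- rownames(train)
  # Orient so the class encoded +1 sits on the positive side of w.x + b.
  dec <- drop(crossprod(train, w)) + b
  pos_class <- names(label_encoding)[label_encoding == 1]
  neg_class <- names(label_encoding)[label_encoding == -1]
  if (mean(dec[labels == pos_class]) < mean(dec[labels == neg_class])) {
    w <- -w
    b <- -b
  }
  model <- structure(
    list(drug = drug, w = w, b = b, feature_ids = rownames(train),
         scaler = scaler, label_encoding = label_encoding, cost = cost,
         tolerance = tolerance, seed = seed, training_accuracy = NA_real_),
    class = "drug_svm")
  preds <- prediction_score(model, train)
  model$training_accuracy <- mean(preds$call == labels[preds$sample_id])
  model
}

#' Drug-sensitivity prediction score
#'
#' Scores samples with the fitted model's decision function under the
#' convention
#' \deqn{\mathrm{score}(x) = -\left(\sum_f w_f x_f + b\right),}
#' where responders are encoded `c = -1`, so a positive score predicts drug
#' sensitivity (call `"R"`) and a negative score predicts resistance
#' (`"NR"`). A score of exactly 0 is called `"NR"`: only strictly positive
#' scores predict response.
#'
#' @param model A fitted `drug_svm`.
#' @param x Scaled sample matrix (features x samples) or a single named
#'   sample vector; must contain every model feature. If the model stores a
#'   scaler and `x` is raw, pass it through [apply_scaler()] first.
#'
#' @return Tibble with one row per sample: `sample_id`, `drug`, `score`,
#'   `call`.
#' @export
prediction_score <- function(model, x) {
  if (!inherits(model, "drug_svm")) {
    abort("`model` must be a fitted drug_svm.",
          class = "chemoresponse_input_error")
  }
  if (!is.matrix(x)) {
    if (is.null(names(x))) {
      abort("A single sample must be a named feature vector.",
            class = "chemoresponse_input_error")
    }
    x <- matrix(x, ncol = 1, dimnames = list(names(x), "sample_1"))
  }
  missing <- setdiff(model$feature_ids, rownames(x))
  if (length(missing)) {
    abort(sprintf("Sample is missing %d model feature(s): %s",
                  length(missing), paste(head(missing, 5), collapse = ", ")),
          class = "chemoresponse_feature_mismatch_error")
  }
  xf <- x[model$feature_ids, , drop = FALSE]
  score <- -(drop(crossprod(xf, model$w)) + model$b)
  # The call rule is fixed: R iff score > 0. Under the default encoding
  # (R = -1) the hyperplane orientation makes responders score positive;
  # negating the encoding negates scores and therefore swaps calls.
  tibble(sample_id = colnames(x), drug = model$drug, score = unname(score),
         call = ifelse(score > 0, "R", "NR"))
}

#' @export
print.drug_svm <- function(x, ...) {
  cat(sprintf("<drug_svm> drug = %s, %d features, cost = %g\n",
              x$drug, length(x$w), x$cost))
  cat(sprintf("  encoding: R = %+d, NR = %+d; training accuracy = %.3f\n",
              x$label_encoding[["R"]], x$label_encoding[["NR"]],
              x$training_accuracy))
  invisible(x)
}

#' @describeIn fit_linear_svm Per-feature weights as a tibble, ranked by
#'   squared weight (the recursive-elimination importance criterion).
#' @param x,... Fitted model and ignored arguments (tidier interface).
#' @method tidy drug_svm
#' @export
tidy.drug_svm <- function(x, ...) {
  ord <- order(-x$w^2, names(x$w))
  tibble(feature = names(x$w)[ord], weight = unname(x$w[ord]),
         rank = seq_along(x$w))
}

#' @describeIn fit_linear_svm One-row model summary.
#' @method glance drug_svm
#' @export
glance.drug_svm <- function(x, ...) {
  tibble(drug = x$drug, n_features = length(x$w), cost = x$cost,
         bias = x$b, training_accuracy = x$training_accuracy)
}
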
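#' Plot a CA-125 trajectory against the normality threshold
#'
#' Marker level over time with the normality threshold (dashed blue) and the
#' treatment start (dashed red), the display used to read off whether a
#' patient's marker normalized after therapy.
#'
#' @param object A `ca125_series`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ca125_series
#' @export
autoplot.ca125_series <- function(object, ...) {
  threshold <- attr(object, "threshold") %||% 35
  ggplot(object, aes(x = .data$time, y = .data$ca125)) +
    geom_line(colour = "grey30") +
    geom_point(aes(colour = .data$phase), size = 2) +
    geom_hline(yintercept = threshold, linetype = "dashed",
               colour = "steelblue") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "firebrick") +
    scale_y_log10() +
    labs(x = "Days from treatment start", y = "CA-125 (U/mL)",
         colour = "Phase") +
    theme_minimal()
}

#' Plot per-sample prediction scores by observed response
#'
#' Strip plot of the decision-function scores with the zero decision
#' boundary: samples right of zero are predicted sensitive, left of zero
#' resistant; colour shows the observed label, so misclassified samples are
#' the off-colour points on each side.
#'
#' @param predictions Tibble with `score` and an observed-label column
#'   (`observed`, or supplied via `observed`).
#' @param observed Optional vector of observed `"R"`/`"NR"` labels.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(predictions, observed = NULL) {
  df <- as_tibble(predictions)
  if (!is.null(observed)) df$observed <- observed
  if (!all(c("score", "observed") %in% names(df))) {
    abort("`predictions` needs `score` and `observed` columns.",
          class = "chemoresponse_input_error")
  }
  ggplot(df, aes(x = .data$score, y = 0, colour = .data$observed)) +
    geom_jitter(height = 0.2, width = 0, size = 2, alpha = 0.8) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    scale_colour_manual(values = c(R = "royalblue", NR = "firebrick")) +
    labs(x = "Prediction score", y = NULL, colour = "Observed") +
    theme_minimal() +
    theme(axis.text.y = ggplot2::element_blank(),
          axis.ticks.y = ggplot2::element_blank())
}

#' Place one patient's drug scores over a cohort score distribution
#'
#' For each drug, the cohort's score distribution is drawn as a density and
#' the patient's own score as a vertical line — the display used to pick
#' promising second-line drugs (scores far right of zero within drugs the
#' patient has not received).
#'
#' @param drug_scores Named numeric vector: the patient's per-drug scores.
#' @param cohort_scores Tibble with `drug` and `score` columns (cohort
#'   distribution per drug).
#' @return A ggplot faceted by drug.
#' @export
plot_score_placement <- function(drug_scores, cohort_scores) {
  if (is.null(names(drug_scores))) {
    abort("`drug_scores` must be named by drug.",
          class = "chemoresponse_input_error")
  }
  patient <- tibble(drug = names(drug_scores), score = unname(drug_scores))
  ggplot(as_tibble(cohort_scores), aes(x = .data$score)) +
    geom_density(fill = "grey80", colour = "grey50") +
    geom_vline(data = patient, aes(xintercept = .data$score),
               colour = "red") +
    geom_vline(xintercept = 0, linetype = "dashed") +
    facet_wrap(~drug) +
    labs(x = "Prediction score", y = "Cohort density") +
    theme_minimal()
}
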
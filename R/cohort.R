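#' Configuration for a synthetic drug-response cohort
#'
#' Bundles and validates the parameters of the cohort simulator. The simulator
#' plants a small set of informative genes whose mean expression differs
#' between responders (R) and non-responders (NR); all remaining genes are
#' label-independent noise. Class sizes are assigned by stratified counting
#' (`round(responder_fraction * n_patients)` responders), so label counts are
#' exact and reproducible rather than binomial draws.
#'
#' @param n_patients Number of patients in the cohort.
#' @param n_genes Number of gene (or probe-set) features.
#' @param n_informative Number of planted informative features
#'   (`<= n_genes`).
#' @param effect_size Mean shift of each informative feature between labels,
#'   in units of that feature's within-class standard deviation.
#' @param responder_fraction Fraction of patients labelled `R`, in (0, 1);
#'   both classes must end up with at least one patient.
#' @param zero_inflation Probability that an expression entry is replaced by
#'   zero (RNA-seq mode only), in \[0, 1).
#' @param platform `"rnaseq"` (non-negative values with dropout zeros) or
#'   `"microarray"` (strictly positive log-normal intensities).
#' @param drug Drug name recorded in the clinical table.
#' @param seed Integer seed; identical configuration and seed reproduce the
#'   cohort bit-for-bit.
#'
#' @return A validated `cohort_config` object (a named list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 100, n_genes = 1000, n_informative = 20,
                          effect_size = 2, responder_fraction = 0.5,
                          zero_inflation = 0.1,
                          platform = c("rnaseq", "microarray"),
                          drug = "gemcitabine", seed = 1) {
  platform <- match.arg(platform)
  bad <- function(field, msg) {
    abort(sprintf("Invalid `%s`: %s", field, msg),
          class = "chemoresponse_config_error")
  }
  if (!is.numeric(n_patients) || n_patients < 2 || n_patients != round(n_patients)) {
    bad("n_patients", "must be an integer >= 2.")
  }
  if (!is.numeric(n_genes) || n_genes < 1 || n_genes != round(n_genes)) {
    bad("n_genes", "must be a positive integer.")
  }
  if (!is.numeric(n_informative) || n_informative < 0 ||
      n_informative != round(n_informative) || n_informative > n_genes) {
    bad("n_informative", "must be an integer in [0, n_genes].")
  }
  if (!is.numeric(effect_size) || effect_size < 0) {
    bad("effect_size", "must be a non-negative number.")
  }
  if (!is.numeric(responder_fraction) || responder_fraction <= 0 ||
      responder_fraction >= 1) {
    bad("responder_fraction", "must lie strictly between 0 and 1.")
  }
  if (round(responder_fraction * n_patients) < 1 ||
      n_patients - round(responder_fraction * n_patients) < 1) {
    bad("responder_fraction", "must leave at least one patient in each class.")
  }
  if (!is.numeric(zero_inflation) || zero_inflation < 0 || zero_inflation >= 1) {
    bad("zero_inflation", "must lie in [0, 1).")
  }
  if (!is.character(drug) || length(drug) != 1L || !nzchar(drug)) {
    bad("drug", "must be a single non-empty drug name.")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    bad("seed", "must be a single integer.")
  }
  structure(
    list(n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
         n_informative = as.integer(n_informative),
         effect_size = as.numeric(effect_size),
         responder_fraction = as.numeric(responder_fraction),
         zero_inflation = as.numeric(zero_inflation), platform = platform,
         drug = drug, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate a drug-response cohort with planted informative genes
#'
#' Generates an expression matrix (features x patients), a clinical table and
#' the ground truth behind both. Responder labels are assigned by stratified
#' counting so class sizes are exact. Informative features receive a mean
#' shift of `effect_size` within-class standard deviations between labels,
#' with a random sign per feature; all other features are label-independent.
#'
#' In `rnaseq` mode, baseline abundances are log-normal, per-feature noise is
#' Gaussian with a constant coefficient of variation, values are clamped at
#' zero, and dropout zeros are injected at rate `zero_inflation`. In
#' `microarray` mode intensities are strictly positive log-normals with the
#' shift applied on the log2 scale (where such data are analysed).
#'
#' @param config A [cohort_config()].
#'
#' @return A `synthetic_cohort` list with elements `expression` (numeric
#'   matrix, features x patients), `clinical` (tibble with `patient_id`,
#'   `drugs`, `response_category`, `label`), `truth_informative` (character),
#'   `truth_labels` (named character) and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, n_genes = 50,
#'                                         n_informative = 5, seed = 7))
#' dim(cohort$expression)
#' table(cohort$clinical$label)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by cohort_config().",
          class = "chemoresponse_config_error")
  }
  with_private_seed(config$seed, {
    n <- config$n_patients
    m <- config$n_genes
    patient_ids <- sprintf("P%03d", seq_len(n))
    gene_ids <- sprintf("g%04d", seq_len(m))

    n_resp <- round(config$responder_fraction * n)
    labels <- rep("NR", n)
    labels[sample.int(n, n_resp)] <- "R"
    names(labels) <- patient_ids

    informative <- sort(sample(gene_ids, config$n_informative))
    shift_sign <- sample(c(-1, 1), config$n_informative, replace = TRUE)

    is_resp <- labels == "R"
    if (config$platform == "rnaseq") {
      mu <- exp(rnorm(m, log(50), 0.8))
      sigma <- 0.3 * mu
      expr <- matrix(rnorm(m * n, mean = mu, sd = sigma), nrow = m,
                     dimnames = list(gene_ids, patient_ids))
      idx <- match(informative, gene_ids)
      if (length(idx)) {
        shift <- config$effect_size * sigma[idx] * shift_sign
        expr[idx, is_resp] <- expr[idx, is_resp] + shift
      }
      expr <- pmax(expr, 0)
      if (config$zero_inflation > 0) {
        drop <- matrix(runif(m * n) < config$zero_inflation, nrow = m)
        expr[drop] <- 0
      }
    } else {
      mu <- rnorm(m, 7, 1.5)       # mean log2 intensity per probe set
      sigma <- rep(0.5, m)         # within-class SD on the log2 scale
      logint <- matrix(rnorm(m * n, mean = mu, sd = sigma), nrow = m,
                       dimnames = list(gene_ids, patient_ids))
      idx <- match(informative, gene_ids)
      if (length(idx)) {
        shift <- config$effect_size * sigma[idx] * shift_sign
        logint[idx, is_resp] <- logint[idx, is_resp] + shift
      }
      expr <- 2^logint
    }

    # Observed TCGA-style response category consistent with the binary label.
    resp_cat <- unname(ifelse(is_resp,
                       sample(c("Complete Response", "Partial Response"), n,
                              replace = TRUE),
                       sample(c("Progressive Disease", "Stable Disease"), n,
                              replace = TRUE)))
    clinical <- tibble(patient_id = patient_ids, drugs = config$drug,
                       response_category = resp_cat, label = unname(labels))

    structure(
      list(expression = expr, clinical = clinical,
           truth_informative = informative, truth_labels = labels,
           config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients x %d features (%s, drug %s)\n",
              x$config$n_patients, x$config$n_genes, x$config$platform,
              x$config$drug))
  cat(sprintf("  labels: %d R / %d NR; %d informative features\n",
              sum(x$truth_labels == "R"), sum(x$truth_labels == "NR"),
              length(x$truth_informative)))
  invisible(x)
}

#' Simulate raw RNA-seq read counts with gene lengths
#'
#' Produces a reproducible set of per-gene, per-sample mapped-read counts
#' (negative binomial around log-normal gene abundances) together with gene
#' lengths in base pairs, as input for upper-quartile FPKM normalization.
#' Every sample is guaranteed at least one zero-count gene so that
#' zero-expression filtering is exercised.
#'
#' @param n_genes Number of genes (at least 4, so a 75th-percentile gene is
#'   defined).
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#'
#' @return A `read_count_set` list with `counts` (integer matrix, genes x
#'   samples) and `gene_lengths` (named integer vector, base pairs).
#' @export
generate_read_counts <- function(n_genes, n_samples, seed = 1) {
  if (!is.numeric(n_genes) || n_genes < 4) {
    abort("`n_genes` must be at least 4 so the 75th-percentile gene exists.",
          class = "chemoresponse_size_error")
  }
  if (!is.numeric(n_samples) || n_samples < 1) {
    abort("`n_samples` must be a positive integer.",
          class = "chemoresponse_size_error")
  }
  n_genes <- as.integer(n_genes)
  n_samples <- as.integer(n_samples)
  with_private_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    abundance <- exp(rnorm(n_genes, log(200), 1.2))
    counts <- matrix(rnbinom(n_genes * n_samples, mu = abundance, size = 2),
                     nrow = n_genes, dimnames = list(gene_ids, sample_ids))
    # guarantee a zero count in every sample (silenced gene)
    for (s in seq_len(n_samples)) {
      if (!any(counts[, s] == 0)) counts[which.min(counts[, s]), s] <- 0L
    }
    lengths <- sample(300:20000, n_genes, replace = TRUE)
    names(lengths) <- gene_ids
    structure(list(counts = counts, gene_lengths = lengths),
              class = "read_count_set")
  })
}

#' Simulate a CA-125 trajectory consistent with a known response
#'
#' CA-125 is a serum tumour marker used to monitor ovarian cancer; values
#' below 35 U/mL are considered normal. The simulated series starts elevated,
#' and after treatment either decays below the threshold (true responders) or
#' stays at or above it (non-responders), so that the threshold rule recovers
#' the planted response.
#'
#' @param true_response `"R"` or `"NR"`.
#' @param threshold Positive normality threshold in U/mL (default 35).
#' @param n_points Number of measurements (default 8).
#' @param treatment_start_index Index of the last pre-treatment measurement
#'   (default 2); later points are post-treatment.
#' @param seed Integer seed.
#'
#' @return A `ca125_series` tibble with columns `time` (days relative to
#'   treatment start), `ca125` (U/mL) and `phase`, carrying `threshold` and
#'   `treatment_start_index` attributes.
#' @seealso [ca125_response()]
#' @export
generate_ca125_series <- function(true_response = c("R", "NR"), threshold = 35,
                                  n_points = 8, treatment_start_index = 2,
                                  seed = 1) {
  true_response <- match.arg(true_response)
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("`threshold` must be a positive CA-125 level (U/mL).",
          class = "chemoresponse_parameter_error")
  }
  if (n_points < treatment_start_index + 1) {
    abort("`n_points` must leave at least one post-treatment measurement.",
          class = "chemoresponse_parameter_error")
  }
  with_private_seed(seed, {
    time <- (seq_len(n_points) - treatment_start_index) * 30
    baseline <- threshold * exp(rnorm(1, log(10), 0.4))   # markedly elevated
    k_post <- seq_len(n_points) - treatment_start_index
    if (true_response == "R") {
      final <- threshold * runif(1, 0.2, 0.8)             # ends below normal
      decay <- (final / baseline)^(1 / max(k_post))
      values <- baseline * decay^pmax(k_post, 0)
      values <- values * exp(rnorm(n_points, 0, 0.05))
      post <- k_post > 0
      if (min(values[post]) >= threshold) {               # noise guard
        values[n_points] <- final
      }
    } else {
      values <- baseline * exp(rnorm(n_points, 0, 0.15))
      post <- k_post > 0
      values[post] <- pmax(values[post], threshold * 1.05)
    }
    out <- tibble(time = time, ca125 = values,
                  phase = ifelse(k_post > 0, "post", "pre"))
    structure(out, class = c("ca125_series", class(out)),
              threshold = threshold,
              treatment_start_index = as.integer(treatment_start_index),
              true_response = true_response)
  })
}

#' Simulate a reference microarray distribution
#'
#' Builds the sorted mean-per-rank vector that one-sample quantile
#' normalization maps new arrays onto. It is a synthetic stand-in for a
#' reference panel of arrays summarised by the mean of each rank's
#' intensities (order statistics averaged across arrays).
#'
#' @param n_features Number of probe-set features (>= 1).
#' @param seed Integer seed.
#'
#' @return Sorted (non-decreasing), strictly positive numeric vector of
#'   length `n_features`.
#' @seealso [quantile_normalize_to_reference()]
#' @export
generate_reference_distribution <- function(n_features, seed = 1) {
  if (!is.numeric(n_features) || n_features < 1) {
    abort("`n_features` must be a positive integer.",
          class = "chemoresponse_size_error")
  }
  with_private_seed(seed, sort(exp(rnorm(as.integer(n_features), log(100), 1))))
}
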
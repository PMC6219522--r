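#' Read / write expression matrices as TSV
#'
#' The on-disk layout is feature rows by sample columns: a header row of
#' sample ids, a first column of feature ids.
#'
#' @param path File path.
#' @return `read_expression_tsv()` returns a numeric matrix (features x
#'   samples); `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  feats <- df[[1]]
  if (anyDuplicated(feats)) {
    abort(sprintf("%s: duplicated feature ids.", path),
          class = "chemoresponse_parse_error")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    abort(sprintf("%s: non-numeric expression values.", path),
          class = "chemoresponse_parse_error")
  }
  rownames(m) <- feats
  m
}

#' @rdname read_expression_tsv
#' @param expr Expression matrix, features x samples.
#' @export
write_expression_tsv <- function(expr, path) {
  assert_expression_matrix(expr)
  df <- dplyr::bind_cols(tibble(feature_id = rownames(expr)),
                         as_tibble(expr))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a two-column gene-length table (feature_id, length_bp)
#'
#' @param path File path.
#' @return Named integer vector of gene lengths in base pairs.
#' @export
read_gene_lengths_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_names = c("feature_id", "length_bp"), skip = 1)
  setNames(as.integer(df$length_bp), df$feature_id)
}

#' Read / write a sorted one-column reference distribution
#'
#' @param path File path.
#' @return Sorted numeric vector.
#' @export
read_reference_distribution <- function(path) {
  v <- as.numeric(readLines(path))
  if (anyNA(v) || is.unsorted(v)) {
    abort(sprintf("%s: reference distribution must be numeric and sorted.",
                  path),
          class = "chemoresponse_parse_error")
  }
  v
}

#' @rdname read_reference_distribution
#' @param ref Sorted numeric vector.
#' @export
write_reference_distribution <- function(ref, path) {
  writeLines(format(ref, digits = 15, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `expression.tsv` (features x samples), `clinical.csv`
#' (`patient_id`, `drugs`, `response_category`, `label`) and `truth.json`
#' (informative features, labels, configuration echo).
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    abort("`cohort` must come from generate_cohort().",
          class = "chemoresponse_input_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  jsonlite::write_json(
    list(truth_informative = cohort$truth_informative,
         truth_labels = as.list(cohort$truth_labels),
         config = unclass(cohort$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `expression`, `clinical`, `truth_informative`,
#'   `truth_labels`.
#' @export
read_cohort <- function(dir) {
  expr <- read_expression_tsv(file.path(dir, "expression.tsv"))
  clinical <- readr::read_csv(file.path(dir, "clinical.csv"),
                              show_col_types = FALSE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(expression = expr, clinical = clinical,
       truth_informative = truth$truth_informative,
       truth_labels = unlist(truth$truth_labels))
}

#' Serialize / restore a fitted drug model as JSON
#'
#' Stores the weight vector, bias, ordered feature list, scaler parameters,
#' label encoding, regularization and seed, so a model reloads bit-exactly.
#'
#' @param model A `drug_svm`.
#' @param path Output JSON path.
#' @return `path` (write) or the restored `drug_svm` (read).
#' @export
write_model_json <- function(model, path) {
  if (!inherits(model, "drug_svm")) {
    abort("`model` must be a drug_svm.", class = "chemoresponse_input_error")
  }
  scaler <- if (!is.null(model$scaler)) {
    list(center = as.list(model$scaler$center),
         scale = as.list(model$scaler$scale),
         log2_transform = model$scaler$log2_transform,
         feature_ids = model$scaler$feature_ids)
  }
  jsonlite::write_json(
    list(drug = model$drug, feature_ids = model$feature_ids,
         w = as.list(model$w), b = model$b,
         label_encoding = as.list(model$label_encoding),
         cost = model$cost, tolerance = model$tolerance, seed = model$seed,
         training_accuracy = model$training_accuracy, scaler = scaler),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  scaler <- NULL
  if (!is.null(m$scaler)) {
    scaler <- structure(
      list(center = unlist(m$scaler$center),
           scale = unlist(m$scaler$scale),
           log2_transform = isTRUE(m$scaler$log2_transform),
           feature_ids = unlist(m$scaler$feature_ids)),
      class = "feature_scaler")
  }
  structure(
    list(drug = m$drug, w = unlist(m$w), b = m$b,
         feature_ids = unlist(m$feature_ids), scaler = scaler,
         label_encoding = unlist(m$label_encoding), cost = m$cost,
         tolerance = m$tolerance,
         seed = if (is.null(m$seed)) NA_integer_ else m$seed,
         training_accuracy = m$training_accuracy),
    class = "drug_svm")
}

#' Write an elimination trace as a two-column TSV
#'
#' @param rfe An `rfe_result` (or its trace tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(rfe, path) {
  trace <- if (inherits(rfe, "rfe_result")) rfe$trace else rfe
  readr::write_tsv(trace[, c("n_features", "accuracy")], path)
  invisible(path)
}
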
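#' Pipeline configuration
#'
#' A single validated configuration drives every pipeline stage; each
#' stochastic stage derives its seed from the explicit `seed` here, so a
#' configuration reproduces its outputs bit-for-bit. The configuration
#' round-trips losslessly through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param out_dir Directory where stages read and write their files.
#' @param platform `"rnaseq"` or `"microarray"` simulation mode.
#' @param n_patients,n_genes,n_informative,effect_size,responder_fraction,zero_inflation,drug
#'   Cohort parameters (see [cohort_config()]).
#' @param max_zero_fraction Zero-expression filter threshold (RNA-seq mode).
#' @param log2_transform Scaler transform convention.
#' @param cost Soft-margin penalty.
#' @param block,floor Elimination schedule parameters.
#' @param train_fraction Train split fraction.
#' @param loocv_mode `"fixed"` or `"nested"`.
#' @param ca125_threshold CA-125 normality threshold (U/mL).
#' @param seed Master integer seed.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("chemoresponse_run_"),
                            platform = c("rnaseq", "microarray"),
                            n_patients = 92, n_genes = 500,
                            n_informative = 20, effect_size = 2,
                            responder_fraction = 0.4, zero_inflation = 0.1,
                            drug = "gemcitabine", max_zero_fraction = 0.25,
                            log2_transform = TRUE, cost = 1, block = 100,
                            floor = 100, train_fraction = 0.75,
                            loocv_mode = c("fixed", "nested"),
                            ca125_threshold = 35, seed = 1) {
  platform <- match.arg(platform)
  loocv_mode <- match.arg(loocv_mode)
  cohort <- cohort_config(n_patients = n_patients, n_genes = n_genes,
                          n_informative = n_informative,
                          effect_size = effect_size,
                          responder_fraction = responder_fraction,
                          zero_inflation = zero_inflation,
                          platform = platform, drug = drug, seed = seed)
  structure(
    c(unclass(cohort),
      list(out_dir = out_dir,
           max_zero_fraction = as.numeric(max_zero_fraction),
           log2_transform = as.logical(log2_transform),
           cost = as.numeric(cost), block = as.integer(block),
           floor = as.integer(floor),
           train_fraction = as.numeric(train_fraction),
           loocv_mode = loocv_mode,
           ca125_threshold = as.numeric(ca125_threshold))),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[setdiff(names(x), character(0))])
}

#' Harmonize drug names via an exact-match synonym table
#'
#' Maps common brand names and shorthands onto canonical generic names
#' (e.g. Taxol to paclitaxel, Carbo to carboplatin); names without a
#' synonym entry are returned trimmed and lower-cased. Matching is exact
#' (after case-folding); no fuzzy matching is attempted.
#'
#' @param x Character vector of drug names.
#' @return Character vector of harmonized names.
#' @examples
#' harmonize_drug_names(c("Taxol", "Carbo", "GEM", "5-FU"))
#' @export
harmonize_drug_names <- function(x) {
  synonyms <- c(taxol = "paclitaxel", carbo = "carboplatin",
                gem = "gemcitabine", cis = "cisplatin",
                "5-fu" = "fluorouracil", "5-fluorouracil" = "fluorouracil",
                adriamycin = "doxorubicin", taxotere = "docetaxel",
                platinol = "cisplatin", iressa = "gefitinib",
                hycamtin = "topotecan", paraplatin = "carboplatin",
                gemzar = "gemcitabine")
  key <- tolower(trimws(x))
  out <- unname(synonyms[key])
  ifelse(is.na(out), key, out)
}

stage_manifest <- function(config, stage, inputs = character(0),
                           outputs = character(0)) {
  digest_files <- function(paths) {
    paths <- paths[file.exists(paths)]
    setNames(as.list(tools::md5sum(paths)), basename(paths))
  }
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("chemoresponse")),
    seed = config$seed,
    config = unclass(config),
    input_md5 = digest_files(inputs),
    output_md5 = digest_files(outputs))
  path <- file.path(config$out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run pipeline stages
#'
#' Each `run_*()` stage reads its inputs from `config$out_dir`, writes its
#' outputs there, and records a manifest (`manifest_<stage>.json`) with the
#' configuration echo, seed, package version and MD5 digests of inputs and
#' outputs; rerunning a stage with an identical configuration reproduces
#' its outputs bit-for-bit.
#'
#' * `run_simulate()` generates the synthetic cohort and writes
#'   `expression.tsv` / `clinical.csv` / `truth.json`.
#' * `run_normalize()` applies the zero-expression filter (RNA-seq mode) or
#'   one-sample quantile normalization against a reference distribution
#'   (microarray mode) and writes `normalized.tsv`.
#' * `run_train()` splits the cohort, fits the scaler on the training
#'   samples, runs recursive feature elimination against the held-out
#'   split, and writes `model.json` and `trace.tsv`.
#' * `run_predict()` scores samples with the stored model (scaler applied
#'   to raw data) and writes `predictions.csv`.
#' * `run_evaluate()` runs LOOCV on the selected features and writes
#'   `evaluation.json` plus the per-sample table `evaluation.csv`.
#'
#' @param config A [pipeline_config()].
#' @return Stage output, invisibly for writers: `run_simulate()` the
#'   cohort, `run_normalize()` the matrix, `run_train()` the `rfe_result`,
#'   `run_predict()` the predictions tibble, `run_evaluate()` the
#'   `confusion_summary`.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(cohort_config(
    n_patients = config$n_patients, n_genes = config$n_genes,
    n_informative = config$n_informative, effect_size = config$effect_size,
    responder_fraction = config$responder_fraction,
    zero_inflation = config$zero_inflation, platform = config$platform,
    drug = config$drug, seed = config$seed))
  write_cohort(cohort, config$out_dir)
  outs <- file.path(config$out_dir,
                    c("expression.tsv", "clinical.csv", "truth.json"))
  stage_manifest(config, "simulate", outputs = outs)
  invisible(cohort)
}

#' @rdname run_simulate
#' @export
run_normalize <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  in_path <- file.path(config$out_dir, "expression.tsv")
  if (!file.exists(in_path)) {
    abort(sprintf("Missing input %s; run run_simulate() first.", in_path),
          class = "chemoresponse_input_error")
  }
  expr <- read_expression_tsv(in_path)
  if (config$platform == "rnaseq") {
    norm <- filter_zero_genes(expr, config$max_zero_fraction)
  } else {
    ref_path <- file.path(config$out_dir, "reference.txt")
    if (!file.exists(ref_path)) {
      write_reference_distribution(
        generate_reference_distribution(nrow(expr), seed = config$seed + 1L),
        ref_path)
    }
    ref <- read_reference_distribution(ref_path)
    norm <- quantile_normalize_to_reference(expr, ref)
  }
  out_path <- file.path(config$out_dir, "normalized.tsv")
  write_expression_tsv(norm, out_path)
  stage_manifest(config, "normalize", inputs = in_path, outputs = out_path)
  invisible(norm)
}

#' @rdname run_simulate
#' @export
run_train <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  expr_path <- file.path(config$out_dir, "normalized.tsv")
  clin_path <- file.path(config$out_dir, "clinical.csv")
  for (p in c(expr_path, clin_path)) {
    if (!file.exists(p)) {
      abort(sprintf("Missing input %s.", p),
            class = "chemoresponse_input_error")
    }
  }
  expr <- read_expression_tsv(expr_path)
  clinical <- readr::read_csv(clin_path, show_col_types = FALSE)
  labels <- setNames(clinical$label, clinical$patient_id)
  if (length(unique(labels)) < 2) {
    abort("Clinical table contains a single response class; cannot train.",
          class = "chemoresponse_degenerate_label_error")
  }
  split <- split_train_test(labels, train_fraction = config$train_fraction,
                            seed = config$seed)
  scaler <- fit_scaler(expr[, split$train, drop = FALSE],
                       log2_transform = config$log2_transform)
  train_scaled <- apply_scaler(scaler, expr[, split$train, drop = FALSE])
  test_scaled <- apply_scaler(scaler, expr[, split$test, drop = FALSE])
  rfe <- rfe_select(train_scaled, labels[split$train], test_scaled,
                    labels[split$test], cost = config$cost,
                    block = config$block, floor = config$floor,
                    drug = config$drug, seed = config$seed)
  rfe$model$scaler <- scaler
  model_path <- file.path(config$out_dir, "model.json")
  trace_path <- file.path(config$out_dir, "trace.tsv")
  feats_path <- file.path(config$out_dir, "selected_features.txt")
  write_model_json(rfe$model, model_path)
  write_trace_tsv(rfe, trace_path)
  writeLines(rfe$selected_features, feats_path)
  stage_manifest(config, "train", inputs = c(expr_path, clin_path),
                 outputs = c(model_path, trace_path, feats_path))
  invisible(rfe)
}

#' @rdname run_simulate
#' @param expr Optional matrix of raw samples to score; defaults to the
#'   run's normalized expression file.
#' @export
run_predict <- function(config, expr = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  model_path <- file.path(config$out_dir, "model.json")
  if (!file.exists(model_path)) {
    abort(sprintf("Missing model %s; run run_train() first.", model_path),
          class = "chemoresponse_input_error")
  }
  model <- read_model_json(model_path)
  if (is.null(expr)) {
    expr <- read_expression_tsv(file.path(config$out_dir, "normalized.tsv"))
  }
  scored <- prediction_score(model, apply_scaler(model$scaler, expr))
  out_path <- file.path(config$out_dir, "predictions.csv")
  readr::write_csv(scored, out_path)
  stage_manifest(config, "predict", inputs = model_path, outputs = out_path)
  invisible(scored)
}

#' @rdname run_simulate
#' @export
run_evaluate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  expr_path <- file.path(config$out_dir, "normalized.tsv")
  clin_path <- file.path(config$out_dir, "clinical.csv")
  model_path <- file.path(config$out_dir, "model.json")
  for (p in c(expr_path, clin_path, model_path)) {
    if (!file.exists(p)) {
      abort(sprintf("Missing input %s.", p),
            class = "chemoresponse_input_error")
    }
  }
  expr <- read_expression_tsv(expr_path)
  clinical <- readr::read_csv(clin_path, show_col_types = FALSE)
  labels <- setNames(clinical$label, clinical$patient_id)
  model <- read_model_json(model_path)
  cm <- loocv(expr, labels, features = model$feature_ids, cost = config$cost,
              mode = config$loocv_mode,
              log2_transform = config$log2_transform,
              block = config$block, floor = config$floor,
              train_fraction = config$train_fraction, seed = config$seed)
  json_path <- file.path(config$out_dir, "evaluation.json")
  csv_path <- file.path(config$out_dir, "evaluation.csv")
  jsonlite::write_json(
    list(drug = config$drug, loocv_mode = config$loocv_mode,
         n_features = length(model$feature_ids),
         counts = list(tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn),
         metrics = as.list(glance(cm)[, c("accuracy", "sensitivity",
                                          "specificity", "ppv", "npv")])),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(attr(cm, "predictions"), csv_path)
  stage_manifest(config, "evaluate",
                 inputs = c(expr_path, clin_path, model_path),
                 outputs = c(json_path, csv_path))
  invisible(cm)
}
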
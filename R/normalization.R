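#' Upper-quartile FPKM normalization of read counts
#'
#' Converts mapped-read counts to FPKM-UQ values,
#' \deqn{\mathrm{FPKM\mbox{-}UQ}(g, s) = \frac{RM_g(g,s) \cdot 10^9}{RM_{75}(s) \cdot L(g)},}
#' where \eqn{RM_g} is the number of reads mapped to gene \eqn{g} in sample
#' \eqn{s}, \eqn{L(g)} the gene length in base pairs, and \eqn{RM_{75}(s)}
#' the count of the sample's 75th-percentile gene. The 75th-percentile gene
#' is the lower-rounded 75th order statistic of the sample's per-gene counts
#' (rank `max(1, floor(0.75 * n_genes))` of the sorted counts), computed over
#' the full feature list. Normalizing by the upper-quartile count rather than
#' the library total makes the value invariant to global per-sample scaling.
#'
#' @param counts A `read_count_set` from [generate_read_counts()], or a
#'   non-negative count matrix (genes x samples) if `gene_lengths` is given.
#' @param gene_lengths Named vector of gene lengths in base pairs; ignored
#'   when `counts` is a `read_count_set`.
#'
#' @return Numeric matrix of FPKM-UQ values, genes x samples.
#' @export
fpkm_uq <- function(counts, gene_lengths = NULL) {
  if (inherits(counts, "read_count_set")) {
    gene_lengths <- counts$gene_lengths
    counts <- counts$counts
  }
  assert_expression_matrix(counts, "counts")
  if (any(counts < 0)) {
    abort("`counts` must be non-negative.", class = "chemoresponse_input_error")
  }
  if (is.null(gene_lengths)) {
    abort("`gene_lengths` is required when `counts` is a bare matrix.",
          class = "chemoresponse_input_error")
  }
  gene_lengths <- gene_lengths[rownames(counts)]
  if (anyNA(gene_lengths) || any(gene_lengths < 1)) {
    abort("`gene_lengths` must cover every gene with length >= 1 bp.",
          class = "chemoresponse_input_error")
  }
  rm75 <- upper_quartile_count(counts)
  zero_uq <- names(rm75)[rm75 == 0]
  if (length(zero_uq)) {
    abort(sprintf(
      "Degenerate sample(s) with zero upper-quartile count: %s",
      paste(zero_uq, collapse = ", ")),
      class = "chemoresponse_degenerate_sample_error")
  }
  sweep(sweep(counts * 1e9, 2, rm75, "/"), 1, as.numeric(gene_lengths), "/")
}

#' Per-sample upper-quartile (75th-percentile gene) count
#'
#' @param counts Count matrix, genes x samples.
#' @return Named numeric vector, one upper-quartile count per sample.
#' @export
upper_quartile_count <- function(counts) {
  idx <- max(1L, floor(0.75 * nrow(counts)))
  apply(counts, 2, function(x) sort(x)[idx])
}

#' Remove genes with too many zero-expression samples
#'
#' A feature is dropped when more than `max_zero_fraction` of the samples
#' show exactly zero expression; a feature with zeros in exactly
#' `max_zero_fraction` of samples is retained (the cut is strict). Feature
#' order and the sample set are preserved.
#'
#' @param expr Expression matrix, features x samples.
#' @param max_zero_fraction Maximum tolerated fraction of zero entries per
#'   feature (default 0.25).
#'
#' @return The filtered expression matrix.
#' @export
filter_zero_genes <- function(expr, max_zero_fraction = 0.25) {
  assert_expression_matrix(expr)
  if (ncol(expr) == 0L || nrow(expr) == 0L) {
    abort("`expr` must be non-empty.", class = "chemoresponse_input_error")
  }
  keep <- rowMeans(expr == 0) <= max_zero_fraction
  if (!any(keep)) {
    abort("All features exceed the zero-expression threshold; nothing retained.",
          class = "chemoresponse_empty_result_error")
  }
  expr[keep, , drop = FALSE]
}

#' One-sample quantile normalization against a reference distribution
#'
#' Replaces each value of a single array by the reference mean-per-rank value
#' at the same rank, so the transformed sample's distribution matches the
#' reference panel's. Tied input values all receive the mean of the reference
#' values over the ranks they jointly occupy, which keeps the map
#' deterministic and order-preserving.
#'
#' @param x Numeric vector (one sample's feature values), or a matrix whose
#'   columns are normalized independently.
#' @param ref Sorted (non-decreasing) reference mean-per-rank vector of the
#'   same length as `x` (or as `nrow(x)`).
#'
#' @return Vector (or matrix) of the same shape with reference-distributed
#'   values.
#' @export
quantile_normalize_to_reference <- function(x, ref) {
  if (is.unsorted(ref)) {
    abort("`ref` must be sorted non-decreasing (a mean-per-rank vector).",
          class = "chemoresponse_input_error")
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, quantile_normalize_to_reference, ref = ref)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (length(x) != length(ref)) {
    abort(sprintf("Sample has %d features but reference has %d ranks.",
                  length(x), length(ref)),
          class = "chemoresponse_shape_error")
  }
  r_min <- rank(x, ties.method = "min")
  r_max <- rank(x, ties.method = "max")
  cs <- c(0, cumsum(ref))
  out <- (cs[r_max + 1] - cs[r_min]) / (r_max - r_min + 1)
  names(out) <- names(x)
  out
}

#' Fit / apply a per-feature training scaler
#'
#' Margin classifiers are sensitive to feature scale, so model inputs are
#' standardized with statistics estimated on training samples only:
#' optionally `log2(x + 1)`, then per-feature centering and unit-variance
#' scaling. A zero-variance feature gets scale 1 (with a warning), so
#' constant features are centered to 0 rather than producing NaN.
#'
#' @param train Training expression matrix, features x samples.
#' @param log2_transform Apply `log2(x + 1)` before standardizing
#'   (default `TRUE`; appropriate for non-negative RNA-seq and intensity
#'   scales).
#'
#' @return A `feature_scaler` holding per-feature center and scale and the
#'   transform convention.
#' @export
fit_scaler <- function(train, log2_transform = TRUE) {
  assert_expression_matrix(train, "train")
  y <- if (log2_transform) log2(train + 1) else train
  center <- rowMeans(y)
  scale <- apply(y, 1, sd)
  flat <- !is.finite(scale) | scale == 0
  if (any(flat)) {
    warn(sprintf("%d zero-variance feature(s); scale set to 1 (e.g. %s).",
                 sum(flat), rownames(train)[which(flat)[1]]))
    scale[flat] <- 1
  }
  structure(list(center = center, scale = scale,
                 log2_transform = log2_transform,
                 feature_ids = rownames(train)),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @param expr Expression matrix to transform; must contain every scaler
#'   feature (extra features are dropped).
#' @export
apply_scaler <- function(scaler, expr) {
  if (!inherits(scaler, "feature_scaler")) {
    abort("`scaler` must be a fitted feature_scaler.",
          class = "chemoresponse_input_error")
  }
  assert_expression_matrix(expr)
  missing <- setdiff(scaler$feature_ids, rownames(expr))
  if (length(missing)) {
    abort(sprintf("`expr` lacks %d scaler feature(s): %s",
                  length(missing),
                  paste(head(missing, 5), collapse = ", ")),
          class = "chemoresponse_feature_mismatch_error")
  }
  y <- expr[scaler$feature_ids, , drop = FALSE]
  if (scaler$log2_transform) y <- log2(y + 1)
  (y - scaler$center) / scaler$scale
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat(sprintf("<feature_scaler> %d features, log2_transform = %s\n",
              length(x$feature_ids), x$log2_transform))
  invisible(x)
}
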
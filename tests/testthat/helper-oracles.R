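# Independent oracles and tiny fixture builders shared across tests.

# Brute-force one-sample quantile normalization: explicit rank lookup with
# mean-of-tied-ranks, written independently of the package's cumsum path.
qn_rank_lookup_oracle <- function(x, ref) {
  lo <- rank(x, ties.method = "min")
  hi <- rank(x, ties.method = "max")
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- mean(ref[seq(lo[i], hi[i])])
  out
}

# Soft-margin linear SVM solved from scratch as the dual box-constrained QP
# (kernlab::ipop interior-point solver), independent of libsvm.
svm_qp_oracle <- function(X, y, C) {
  n <- nrow(X)
  H <- (y %*% t(y)) * (X %*% t(X)) + diag(1e-10, n)
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = t(y), b = 0, r = 0,
                       l = rep(0, n), u = rep(C, n), sigf = 12, maxiter = 200)
  alpha <- kernlab::primal(sol)
  w <- drop(t(X) %*% (alpha * y))
  on_margin <- alpha > 1e-6 * C & alpha < C * (1 - 1e-6)
  b <- mean(y[on_margin] - X[on_margin, , drop = FALSE] %*% w)
  list(w = w, b = b)
}

# Two well-separated Gaussian clusters in feature-major layout, pre-scaled.
make_separable_toy <- function(n_per_class = 6, p = 4, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c("R", "NR"), each = n_per_class)
    x <- matrix(rnorm(p * n), nrow = p,
                dimnames = list(sprintf("f%02d", seq_len(p)),
                                sprintf("s%02d", seq_len(n))))
    x[, labels == "R"] <- x[, labels == "R"] + gap / 2
    x[, labels == "NR"] <- x[, labels == "NR"] - gap / 2
    names(labels) <- colnames(x)
    list(x = x, labels = labels)
  })
}

# Small RNA-seq style cohort ready for model fitting.
make_scaled_cohort <- function(n_patients = 40, n_genes = 60,
                               n_informative = 5, effect_size = 3,
                               seed = 3, split_seed = 2,
                               zero_inflation = 0.05) {
  cohort <- generate_cohort(cohort_config(
    n_patients = n_patients, n_genes = n_genes,
    n_informative = n_informative, effect_size = effect_size,
    responder_fraction = 0.5, zero_inflation = zero_inflation, seed = seed))
  labels <- cohort$truth_labels
  expr <- filter_zero_genes(cohort$expression)
  split <- split_train_test(labels, seed = split_seed)
  scaler <- fit_scaler(expr[, split$train])
  list(cohort = cohort, labels = labels,
       train = apply_scaler(scaler, expr[, split$train]),
       test = apply_scaler(scaler, expr[, split$test]),
       raw = expr, split = split)
}
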
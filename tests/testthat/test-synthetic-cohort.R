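test_that("cohort configuration rejects invalid fields by name", {
  expect_error(cohort_config(n_informative = 30, n_genes = 20),
               "n_informative", class = "chemoresponse_config_error")
  expect_error(cohort_config(responder_fraction = 1),
               "responder_fraction", class = "chemoresponse_config_error")
  expect_error(cohort_config(n_patients = 100, responder_fraction = 0.001),
               "responder_fraction", class = "chemoresponse_config_error")
  expect_error(cohort_config(zero_inflation = 1),
               "zero_inflation", class = "chemoresponse_config_error")
  expect_error(cohort_config(effect_size = -1),
               "effect_size", class = "chemoresponse_config_error")
  expect_error(cohort_config(seed = NA),
               "seed", class = "chemoresponse_config_error")
})

test_that("cohorts are bit-reproducible with exact stratified label counts", {
  cfg <- cohort_config(n_patients = 92, n_genes = 30, n_informative = 3,
                       responder_fraction = 37 / 92, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(table(a$truth_labels)[["R"]], 37L)
  expect_identical(table(a$truth_labels)[["NR"]], 55L)

  # sample ids agree between expression and clinical; truth is a subset
  expect_setequal(colnames(a$expression), a$clinical$patient_id)
  expect_true(all(a$truth_informative %in% rownames(a$expression)))
  expect_true(all(a$expression >= 0))

  none <- generate_cohort(cohort_config(n_patients = 10, n_genes = 10,
                                        n_informative = 0, seed = 1))
  expect_length(none$truth_informative, 0)
})

test_that("clinical response categories are consistent with the binary label", {
  co <- generate_cohort(cohort_config(n_patients = 30, n_genes = 10,
                                      n_informative = 0, seed = 4))
  expect_identical(binarize_response(co$clinical$response_category),
                   unname(co$truth_labels[co$clinical$patient_id]))
})

test_that("microarray mode yields strictly positive intensities", {
  co <- generate_cohort(cohort_config(n_patients = 20, n_genes = 40,
                                      n_informative = 4,
                                      platform = "microarray", seed = 2))
  expect_true(all(co$expression > 0))
})

test_that("a null cohort's per-gene t statistics follow the null distribution", {
  co <- generate_cohort(cohort_config(n_patients = 100, n_genes = 2000,
                                      n_informative = 0, effect_size = 0,
                                      responder_fraction = 0.5,
                                      zero_inflation = 0, seed = 11))
  g <- co$truth_labels == "R"
  tstat <- apply(co$expression, 1, function(v) {
    stats::t.test(v[g], v[!g], var.equal = TRUE)$statistic
  })
  ks <- stats::ks.test(tstat, stats::pt, df = 98)
  expect_gt(ks$p.value, 0.01)
})

test_that("planted informative genes shift means by the configured effect", {
  effect <- 2
  co <- generate_cohort(cohort_config(n_patients = 500, n_genes = 200,
                                      n_informative = 20,
                                      effect_size = effect,
                                      responder_fraction = 0.5,
                                      zero_inflation = 0, seed = 5))
  g <- co$truth_labels == "R"
  inf <- co$truth_informative
  diff <- abs(rowMeans(co$expression[inf, g]) -
                rowMeans(co$expression[inf, !g]))
  sd_within <- apply(co$expression[inf, !g], 1, sd)
  ratio <- diff / (effect * sd_within)
  expect_lt(abs(mean(ratio) - 1), 0.05)   # calibrated on average
  expect_true(all(ratio > 0.7 & ratio < 1.3))  # per-gene Monte-Carlo error
})

test_that("read-count sets are reproducible with zeros in every sample", {
  a <- generate_read_counts(50, 6, seed = 2)
  b <- generate_read_counts(50, 6, seed = 2)
  expect_identical(a, b)
  expect_true(all(a$counts >= 0))
  expect_true(all(a$gene_lengths >= 1))
  expect_true(all(apply(a$counts, 2, function(x) any(x == 0))))

  tiny <- generate_read_counts(4, 2, seed = 1)
  expect_length(upper_quartile_count(tiny$counts), 2)
  expect_error(generate_read_counts(3, 2), class = "chemoresponse_size_error")
})

test_that("CA-125 series honour the threshold contract and round-trip", {
  r <- generate_ca125_series("R", threshold = 35, seed = 1)
  expect_lt(min(r$ca125[r$phase == "post"]), 35)
  nr <- generate_ca125_series("NR", threshold = 35, seed = 1)
  expect_true(all(nr$ca125[nr$phase == "post"] >= 35))
  expect_error(generate_ca125_series("R", threshold = 0),
               class = "chemoresponse_parameter_error")

  # 200 simulated patients all classified back to their true response
  truth <- rep(c("R", "NR"), 100)
  recovered <- vapply(seq_along(truth), function(i) {
    ca125_response(generate_ca125_series(truth[i], seed = i))
  }, character(1))
  expect_identical(recovered, truth)
})

test_that("reference distributions are sorted, positive and seed-sensitive", {
  ref <- generate_reference_distribution(100, seed = 1)
  expect_length(ref, 100)
  expect_true(all(ref > 0))
  expect_false(is.unsorted(ref))
  expect_false(identical(ref, generate_reference_distribution(100, seed = 2)))
  expect_error(generate_reference_distribution(0),
               class = "chemoresponse_size_error")
})
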
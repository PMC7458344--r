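test_that("Spearman correlation handles monotone, reversed and tied inputs", {
  expect_equal(spearman_cor(c(1, 2, 3), c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(30, 20, 10))$rho, -1)
  # hand computation: d^2 sum = 2, rho = 1 - 6*2/(3*8) = 0.5
  expect_equal(spearman_cor(c(1, 2, 3), c(2, 1, 3))$rho, 0.5)
  expect_error(spearman_cor(c(1, 2), c(3, 4)), "3 complete pairs")
  expect_warning(r <- spearman_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r$rho))
  # pairs with a missing member are dropped and the complete count reported
  r2 <- spearman_cor(c(1, 2, NA, 4, 5), c(4, 3, 2, NA, 1))
  expect_equal(r2$n, 3)
  expect_equal(r2$rho, -1)
})

test_that("Spearman with ties matches the average-rank oracle", {
  set.seed(5)
  for (rep in 1:20) {
    x <- sample(1:5, 15, replace = TRUE)
    y <- sample(1:5, 15, replace = TRUE)
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    expect_equal(spearman_cor(x, y)$rho, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("Pearson matrix is symmetric with unit diagonal and exact small cases", {
  mat <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = -c(1, 2, 3, 4))
  cm <- pearson_matrix(mat)
  expect_equal(diag(cm), c(a = 1, b = 1, c = 1))
  expect_equal(cm, t(cm))
  expect_equal(cm["a", "b"], 0.8)   # direct covariance/sd computation
  expect_equal(cm["a", "c"], -1)
  expect_warning(cm2 <- pearson_matrix(rbind(k = c(2, 2, 2), a = c(1, 2, 3))),
                 "constant")
  expect_true(all(is.na(cm2["k", ])))
})

test_that("permutation report obeys the add-one empirical p rule", {
  toy <- toy_concordant_decon()
  rep1 <- permutation_significance(toy$decon, toy$ihc, toy$mapping, "M",
                                   n_perm = 50L, seed = 7L)
  expect_length(rep1$permuted_rhos, 50)
  expect_equal(rep1$empirical_p,
               (1 + sum(rep1$permuted_rhos >= rep1$observed_rho)) / 51)
  expect_gt(rep1$empirical_p, 0)
  expect_lte(rep1$empirical_p, 1)
  # same seed reproduces, different seed perturbs the permutation draws
  rep2 <- permutation_significance(toy$decon, toy$ihc, toy$mapping, "M",
                                   n_perm = 50L, seed = 7L)
  expect_identical(rep1$permuted_rhos, rep2$permuted_rhos)
  rep3 <- permutation_significance(toy$decon, toy$ihc, toy$mapping, "M",
                                   n_perm = 50L, seed = 8L)
  expect_false(identical(sort(rep1$permuted_rhos), sort(rep3$permuted_rhos)))
})

test_that("default permutation counts follow catalog size", {
  co <- simulate_cohort(sim_config(n_patients = 20L, n_genes = 10L,
                                   n_signature_genes = 2L, seed = 13L))
  ihc <- setNames(co$ihc$cd3, co$ihc$patient)
  r22 <- permutation_significance(co$decon$cibersort_lm22, ihc,
                                  default_mapping("cibersort_lm22"), "CD3",
                                  seed = 1L)
  expect_equal(r22$n_perm, 20L)
  r64 <- permutation_significance(co$decon$xcell64, ihc,
                                  default_mapping("xcell64"), "CD3", seed = 1L)
  expect_equal(r64$n_perm, 100L)
})

test_that("catalog smaller than the constituent set is rejected", {
  toy <- toy_concordant_decon()
  small <- composite_mapping("toy", list(M = c("type1", "type2")),
                             toy$mapping$catalog)
  small$catalog <- "type1"
  expect_error(permutation_significance(toy$decon, toy$ihc, small, "M",
                                        n_perm = 5L),
               "smaller than")
  expect_error(permutation_significance(toy$decon, toy$ihc, toy$mapping, "CD3"),
               "not defined")
})

test_that("percent match is the row-referenced overlap percentage", {
  sets <- list(A = c("g1", "g2"), B = c("g2", "g3"), C = c("x1", "x2", "x3"))
  pm <- percent_match(sets)
  expect_equal(diag(pm), c(A = 100, B = 100, C = 100))
  expect_equal(pm["A", "B"], 50)
  expect_equal(pm["A", "C"], 0)
  expect_true(all(pm >= 0 & pm <= 100))
  # asymmetry by design: |A n B|/|A| vs /|B|
  sets2 <- list(A = c("g1", "g2", "g3", "g4"), B = c("g1", "g2"))
  pm2 <- percent_match(sets2)
  expect_equal(pm2["A", "B"], 50)
  expect_equal(pm2["B", "A"], 100)
  # Jaccard option is symmetric
  pmj <- percent_match(sets2, jaccard = TRUE)
  expect_equal(pmj["A", "B"], pmj["B", "A"])
  expect_equal(pmj["A", "B"], 50)
  expect_error(percent_match(sets["A"]), "at least 2")
})
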
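make_expr <- function(mat) {
  expression_matrix(mat, transform = "normalized_log")
}

test_that("class assignment follows the double-high / double-low rule", {
  ihc <- data.frame(patient = paste0("P", 1:6),
                    cd3 = c(90, 80, 10, 20, 85, NA),
                    cd8 = c(50, 60, 4, 3, 45, 10),
                    cd68 = 1, time = 1, event = TRUE)
  # median cutoffs: cd3 > 80, cd8 > 27.5
  cls <- assign_classes(ihc, strat_rule("median"), strat_rule("median"))
  expect_equal(unname(cls[c("P1", "P5")]), c("HI", "HI"))
  expect_equal(unname(cls[c("P3", "P4")]), c("LOW", "LOW"))
  expect_equal(unname(cls["P2"]), "excluded")   # discordant markers
  expect_equal(unname(cls["P6"]), "excluded")   # missing density
})

test_that("HI fraction under independent densities matches the probability product", {
  set.seed(77)
  n <- 20000
  ihc <- data.frame(patient = seq_len(n), cd3 = rlnorm(n), cd8 = rlnorm(n),
                    cd68 = 1, time = 1, event = TRUE)
  cls <- assign_classes(ihc)  # cd3 75th percentile, cd8 median
  expect_equal(mean(cls == "HI"), 0.25 * 0.5, tolerance = 0.02)
})

test_that("pooled t-test matches the from-scratch oracle to high precision", {
  # hand case: (1,2,3,4) vs (3,4,5,6), pooled, 6 df
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  orc <- oracle_pooled_t(a, b)
  expect_equal(orc$t, -2.1909, tolerance = 1e-4)
  mat <- rbind(g1 = c(a, b))
  colnames(mat) <- paste0("S", 1:8)
  sig <- ttest_per_gene(make_expr(mat),
                        rep(c("HI", "LOW"), each = 4), variant = "pooled",
                        alpha = 0.05)
  expect_equal(sig$t, orc$t, tolerance = 1e-10)
  expect_equal(sig$p, orc$p, tolerance = 1e-10)
  expect_equal(sig$p, 0.0707, tolerance = 1e-2)
  expect_equal(sig$direction, "up_in_LOW")

  set.seed(91)
  for (rep in 1:20) {
    m <- matrix(rnorm(30, sd = runif(1, 0.5, 3)), 1, 30)
    colnames(m) <- paste0("S", 1:30)
    rownames(m) <- "g"
    lab <- rep(c("HI", "LOW"), c(12, 18))
    got <- ttest_per_gene(make_expr(m), lab, variant = "pooled")
    want <- oracle_pooled_t(m[1, 1:12], m[1, 13:30])
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("degenerate genes are withheld and alpha is monotone", {
  mat <- rbind(flat = rep(2, 8), ok = c(rnorm(4, 5), rnorm(4, 0)))
  colnames(mat) <- paste0("S", 1:8)
  lab <- rep(c("HI", "LOW"), each = 4)
  expect_message(sig <- ttest_per_gene(make_expr(mat), lab), "flat")
  expect_true(is.na(sig$p[sig$gene == "flat"]))
  expect_false(sig$selected[sig$gene == "flat"])

  fx <- load_tcell_fixture()
  counts <- vapply(c(1e-6, 1e-4, 1e-3, 0.05),
                   function(a) sum(ttest_per_gene(fx$expr, fx$classes,
                                                  alpha = a)$selected),
                   1L)
  expect_true(all(diff(counts) >= 0))
  # alpha = 0 selects nothing
  sig0 <- ttest_per_gene(fx$expr, fx$classes, alpha = 0)
  expect_length(suppressWarnings(select_signature(sig0)), 0)
})

test_that("direction filter splits the fixture signature as published", {
  fx <- load_tcell_fixture()
  sig <- ttest_per_gene(fx$expr, fx$classes, variant = "pooled", alpha = 0.001)
  low_genes <- select_signature(sig, "up_in_LOW")
  expect_true(all(c("FAM3C", "NEBL", "HSP90AB1", "CSTB") %in% low_genes))
  expect_false("IL7R" %in% low_genes)
  hi_genes <- select_signature(sig, "up_in_HI")
  expect_true(all(c("IL7R", "CD3E", "CTLA4", "SLAMF6") %in% hi_genes))
  expect_equal(sort(c(low_genes, hi_genes)), sort(select_signature(sig)))
  # selection list is ordered by ascending p
  both <- select_signature(sig)
  expect_equal(both, sig$gene[order(sig$p)][seq_along(both)])
})

test_that("label permutation rarely beats the true class split on the fixture", {
  fx <- load_tcell_fixture()
  true_n <- sum(ttest_per_gene(fx$expr, fx$classes)$selected)
  set.seed(29)
  perm_n <- replicate(200, {
    sum(suppressMessages(
      ttest_per_gene(fx$expr, sample(unname(fx$classes)))$selected))
  })
  expect_gte(mean(perm_n < true_n), 0.95)
})

test_that("z-scores standardize against the reference with sample sd", {
  mat <- rbind(g = c(1, 2, 3, 4))
  colnames(mat) <- c("r1", "r2", "r3", "q")
  z <- zscore_vs_reference(make_expr(mat), reference_samples = c("r1", "r2", "r3"))
  expect_equal(unname(z["g", "q"]), 2)   # (4 - 2) / sd(1,2,3) = 2/1
  expect_equal(unname(z["g", "r2"]), 0)
  # reference columns standardize to mean 0, sd 1
  expect_equal(mean(z["g", 1:3]), 0)
  expect_equal(sd(z["g", 1:3]), 1)

  flat <- rbind(k = rep(1, 4)); colnames(flat) <- colnames(mat)
  expect_true(all(is.na(zscore_vs_reference(make_expr(flat)))))
  expect_error(zscore_vs_reference(make_expr(mat), c("r1", "r2")), ">= 3")
})

test_that("enrichment calls trigger on any gene at the threshold and are monotone", {
  z <- rbind(gA = c(2.5, 1.9, 1.0), gB = c(0.1, 1.9, 2.0))
  colnames(z) <- paste0("S", 1:3)
  calls <- classify_enriched(z, c("gA", "gB"), threshold = 2)
  expect_equal(calls$enriched, c(TRUE, FALSE, TRUE))
  expect_equal(calls$triggering_genes[1], "gA")
  expect_error(classify_enriched(z, "gZ"), "no signature gene")

  # monotone: raising any signature z never flips enriched -> not enriched
  set.seed(33)
  for (rep in 1:10) {
    zz <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("S", 1:4)))
    before <- classify_enriched(zz, rownames(zz))$enriched
    zz[sample(3, 1), ] <- zz[sample(3, 1), ] + runif(1, 0, 3)
    after <- classify_enriched(zz, rownames(zz))$enriched
    expect_true(all(after >= before))
  }
})

test_that("enrichment classification detects planted high-infiltration samples", {
  set.seed(57)
  n_ref <- 40; n_pos <- 20
  genes <- paste0("g", 1:5)
  ref <- matrix(rnorm(5 * n_ref, 5, 1), 5, n_ref,
                dimnames = list(genes, paste0("R", 1:n_ref)))
  pos <- matrix(rnorm(5 * n_pos, 5, 1), 5, n_pos,
                dimnames = list(genes, paste0("Q", 1:n_pos)))
  pos[1:3, ] <- pos[1:3, ] + 3   # effect >= 3 reference sds on 3 genes
  expr <- make_expr(cbind(ref, pos))
  z <- zscore_vs_reference(expr, reference_samples = colnames(ref))
  calls <- classify_enriched(z, genes, threshold = 2)
  sens <- mean(calls$enriched[calls$sample %in% colnames(pos)])
  expect_gte(sens, 0.9)
})

test_that("signature genes out-correlate background genes with latent infiltration", {
  co <- simulate_cohort(sim_config(n_patients = 80L, n_genes = 300L,
                                   n_signature_genes = 20L, effect_size = 2,
                                   seed = 21L))
  lg <- log_transform(co$expression)
  infil <- rbind(cd3_latent = co$truth$latent$cd3)
  colnames(infil) <- co$truth$latent$patient
  res <- signature_infiltrate_correlation(lg, infil,
                                          signature_genes = rownames(lg))
  expect_equal(dim(res$correlation), c(301L, 301L))
  rs <- res$correlation["cd3_latent", rownames(lg)]
  planted <- names(rs) %in% co$truth$planted_genes
  expect_gt(median(rs[planted]) - median(rs[!planted]), 0.3)
  expect_error(signature_infiltrate_correlation(lg, infil[, 1:2, drop = FALSE]),
               "shared")
})
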
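test_that("stratification uses a strict greater-than cutoff", {
  s1 <- stratify(c(1, 2, 3, 4), strat_rule("median"))
  expect_equal(as.character(s1), c("low", "low", "high", "high"))
  # tie with the cutoff falls low
  s2 <- stratify(c(1, 2, 2, 3), strat_rule("median"))
  expect_equal(as.character(s2), c("low", "low", "low", "high"))
  # linear-interpolation percentile on 1..100: cutoff 75.25, 25 values above
  s3 <- stratify(1:100, strat_rule("percentile", 75))
  expect_equal(sum(s3 == "high"), 25)
  expect_equal(attr(s3, "cutoff"), unname(quantile(1:100, 0.75)))
  # missing values propagate, degenerate split warns
  expect_true(is.na(stratify(c(1, NA, 3), strat_rule("median"))[2]))
  expect_warning(s4 <- stratify(c(2, 2, 2)), "degenerate")
  expect_true(all(s4 == "low"))
  expect_error(strat_rule("percentile", 100), "q must")
})

test_that("Kaplan-Meier estimate is the product-limit step function", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: survival never drops
  km2 <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(km2$surv == 1))
  # single record with an event: immediate drop to 0
  expect_equal(km_estimate(5, TRUE)$surv, 0)
})

test_that("Kaplan-Meier matches the brute-force oracle on random instances", {
  set.seed(27)
  for (rep in 1:10) {
    n <- 30
    time <- round(rexp(n, 0.1), 1)
    event <- runif(n) < 0.7
    if (!any(event)) next
    km <- km_estimate(time, event)
    orc <- oracle_km(time, event)
    got <- km$surv[km$n_event > 0]
    expect_equal(got, orc$surv, tolerance = 1e-12)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_equal(km$surv[1] <= 1, TRUE)
  }
})

test_that("log-rank test agrees with the hand-computed O-E/V form", {
  # identical groups: exchangeable, no signal
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                      rep(c("a", "b"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # A events at 1,2; B censored at 5,6
  time <- c(1, 2, 5, 6); event <- c(TRUE, TRUE, FALSE, FALSE)
  group <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, group)
  orc <- oracle_logrank(time, event, group)
  expect_equal(lr$chisq, orc$chisq, tolerance = 1e-10)
  expect_equal(lr$p, orc$p, tolerance = 1e-10)

  # label swap leaves the statistic unchanged
  lr_sw <- logrank_test(time, event, c("B", "B", "A", "A"))
  expect_equal(lr_sw$chisq, lr$chisq)

  set.seed(15)
  for (rep in 1:10) {
    n <- 40
    time <- round(rexp(n, 0.05), 1)
    event <- runif(n) < 0.8
    group <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(group)) < 2 || !any(event)) next
    expect_equal(logrank_test(time, event, group)$chisq,
                 oracle_logrank(time, event, group)$chisq, tolerance = 1e-8)
  }

  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "2 groups")
})

test_that("two-factor survival reports per-stratum comparisons and bookkeeping", {
  set.seed(51)
  n <- 80
  primary <- rlnorm(n)
  secondary <- rlnorm(n)
  time <- rexp(n, 0.1); event <- runif(n) < 0.8
  tf <- two_factor_survival(time, event, primary, secondary,
                            strat_rule("median"), strat_rule("median"))
  expect_equal(nrow(tf), 2)
  # conservation: four cells sum to the doubly-labelled patient count
  expect_equal(sum(tf$n_secondary_high) + sum(tf$n_secondary_low), n)
  expect_true(all(is.na(tf$p) | (tf$p > 0 & tf$p <= 1)))

  # constant secondary labels inside a stratum are skipped, not an error
  sec_const <- c(rep(0, n / 2), rlnorm(n / 2))
  tf2 <- two_factor_survival(time, event, sort(primary), sec_const,
                             strat_rule("median"), strat_rule("median"))
  expect_true(any(grepl("skipped", tf2$note)) || all(!is.na(tf2$p)))
})

test_that("survival_by_cutoff ties stratification to the log-rank comparison", {
  set.seed(63)
  n <- 120
  val <- rlnorm(n)
  # hazard falls with the variable: high group should do better
  time <- rexp(n, 0.2 * exp(-1.5 * scale(log(val))[, 1]))
  event <- rep(TRUE, n)
  res <- survival_by_cutoff(time, event, val, strat_rule("median"))
  expect_lt(res$logrank$p, 0.01)
  expect_equal(unname(res$logrank$n), c(60, 60))
  km_high <- res$curves$high
  expect_true(all(diff(km_high$surv) <= 1e-12))
})
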
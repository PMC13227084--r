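test_that("noise-free outcome recovers the exact group effect and flags degeneracy", {
  set.seed(1)
  g <- rep(c(0, 1), each = 10)
  age <- runif(20, 60, 90)
  sex <- sample(c(0, 1), 20, replace = TRUE)
  fit <- fit_adjusted(5 * g, g, age, sex)
  expect_equal(fit$beta, 5)
  expect_lt(fit$se, 1e-8)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$p))
})

test_that("adjusted model matches a normal-equations solve on a fixed 8-row fixture", {
  y <- c(12.1, 9.4, 15.2, 11.8, 18.9, 16.4, 14.0, 20.3)
  g <- c(0, 0, 0, 0, 1, 1, 1, 1)
  age <- c(62, 71, 68, 75, 66, 80, 73, 69)
  sex <- c(1, 0, 1, 0, 1, 0, 0, 1)
  fit <- fit_adjusted(y, g, age, sex)
  ref <- reference_ols_group(y, g, age, sex)
  expect_equal(fit$beta, ref$beta, tolerance = 1e-10)
  expect_equal(fit$se, ref$se, tolerance = 1e-10)
  expect_equal(fit$p, ref$p, tolerance = 1e-10)
  expect_true(fit$ci_low <= fit$beta && fit$beta <= fit$ci_high)
})

test_that("adjusted model matches the normal-equations oracle on random designs", {
  set.seed(104)
  for (k in 1:50) {
    n <- sample(20:200, 1)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) g[1:2] <- c(0, 1)
    age <- runif(n, 60, 90)
    sex <- rbinom(n, 1, 0.6)
    y <- 2 + 3 * g - 0.1 * age + sex + rnorm(n)
    fit <- fit_adjusted(y, g, age, sex)
    ref <- reference_ols_group(y, g, age, sex)
    expect_equal(fit$beta, ref$beta, tolerance = 1e-8)
    expect_equal(fit$se, ref$se, tolerance = 1e-8)
  }
})

test_that("adjusted model rejects degenerate inputs", {
  expect_error(fit_adjusted(1:10, rep(1, 10), 1:10, rep(0, 10)), "both levels")
  expect_error(fit_adjusted(1:4, c(0, 1, 0, 1), 1:4, c(0, 1, 0, 1)),
               "at least 5")
  expect_error(fit_adjusted(1:6, c(0, 1, 0, 1, 0, 1), 1:5, c(0, 1, 0, 1, 0, 1)),
               "equal lengths")
})

test_that("factor codings map altered and female to 1", {
  set.seed(6)
  n <- 60
  g <- sample(c("normal", "altered"), n, replace = TRUE)
  s <- sample(c("male", "female"), n, replace = TRUE)
  age <- runif(n, 60, 90)
  y <- 10 + 4 * (g == "altered") + rnorm(n, 0, 0.1)
  fit <- fit_adjusted(y, g, age, s)
  expect_gt(fit$beta, 3)   # positive = higher in the altered group
})

test_that("Mann-Whitney exact p matches full enumeration for separated triples", {
  res <- unadjusted_test(c(1, 2, 3), c(4, 5, 6), test = "mann_whitney")
  expect_equal(res$test, "mann_whitney")
  # complete separation: 2 of the choose(6,3)=20 assignments are as extreme
  expect_equal(res$p, 0.1, tolerance = 1e-12)
})

test_that("identical groups give p approximately 1", {
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  res <- unadjusted_test(y, y, test = "mann_whitney")
  expect_equal(res$p, 1, tolerance = 1e-8)
})

test_that("test selection follows per-group normality", {
  set.seed(33)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(unadjusted_test(a, b)$test, "welch_t")
  expect_equal(unadjusted_test(exp(rnorm(100, 0, 2)), b)$test, "mann_whitney")
  expect_error(unadjusted_test(1:2, 1:5), "at least 3")
})

test_that("unadjusted rejection rate under the null is close to alpha", {
  set.seed(55)
  rej <- replicate(400, unadjusted_test(rnorm(50), rnorm(50))$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("Pearson chi-square matches hand arithmetic", {
  t0 <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square_test(t0)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # identical rows => independence by construction
  res <- chi_square_test(rbind(c(5, 7, 9), c(5, 7, 9)))
  expect_equal(res$statistic, 0, tolerance = 1e-12)

  # published age-band x group counts vs manual expected-count arithmetic
  counts <- printed_age_group_counts()
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  stat_manual <- sum((counts - expected)^2 / expected)
  res <- chi_square_test(counts)
  expect_equal(res$statistic, stat_manual, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_error(chi_square_test(rbind(c(0, 0), c(1, 2))), "positive")
  expect_error(chi_square_test(rbind(c(-1, 2), c(1, 2))), "non-negative")
})

test_that("log transform triggers only for nonnormal positive outcomes", {
  set.seed(200)
  y_norm <- rnorm(200)
  r <- maybe_log_transform(y_norm)
  expect_false(r$log_transformed)
  expect_identical(r$values, y_norm)

  y_lnorm <- exp(rnorm(200, 0, 1))
  r <- maybe_log_transform(y_lnorm)
  expect_true(r$log_transformed)
  expect_equal(r$values, log(y_lnorm))
  # the transformed values pass the same normality check
  expect_gt(shapiro.test(r$values)$p.value, 0.05)

  y0 <- c(y_lnorm[-1], 0)
  r <- maybe_log_transform(y0)
  expect_false(r$log_transformed)
  expect_true(r$warning)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  for (k in 1:200) {
    p <- runif(sample(1:200, 1))
    adj <- bh_adjust(p)
    expect_identical(adj, reference_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("run_analysis returns one result per family variable", {
  co <- generate_cohort(cohort_config(seed = 12))
  res <- run_analysis(co$feature_table, cfg = analysis_config(transform = FALSE))
  expect_equal(nrow(res$results), 80L)
  expect_identical(res$results$variable, handwriting_variable_names())
  expect_true(all(res$results$p_fdr >= res$results$p_raw - 1e-15))
  expect_true(all(res$results$ci_low <= res$results$beta &
                    res$results$beta <= res$results$ci_high))
  expect_equal(dim(res$counts), c(3L, 8L))
  expect_true(all(res$counts[1, ] <= 2) && all(res$counts[2:3, ] <= 4))

  # physical variables join the family only when configured
  res2 <- run_analysis(co$feature_table, co$physical,
                       cfg = analysis_config(family = "handwriting_plus_physical",
                                             transform = FALSE))
  expect_gt(nrow(res2$results), 80L)
})

test_that("planted effects localize to the planted cells", {
  hp <- default_handwriting_params()
  # null out every group difference, then plant large temporal effects in
  # the two mechanical tasks T8/T9 only
  hp$mu_altered <- hp$mu_normal
  for (v in c("T8_time_down", "T8_time_on_air", "T9_time_down",
              "T9_time_on_air")) {
    i <- hp$variable == v
    hp$mu_altered[i] <- hp$mu_normal[i] + 8 * hp$sigma_normal[i]
  }
  co <- generate_cohort(cohort_config(handwriting_params = hp, seed = 99))
  res <- run_analysis(co$feature_table, cfg = analysis_config(transform = FALSE))
  counts <- res$counts
  expect_equal(counts["mechanical", "time_down"], 2L)
  expect_equal(counts["mechanical", "time_on_air"], 2L)
  other <- counts
  other["mechanical", c("time_down", "time_on_air")] <- 0L
  expect_true(all(other == 0L))
})

test_that("count matrix computed from the published FDR p-values matches the published tally", {
  printed <- printed_handwriting_stats()
  counts <- significance_count_matrix(printed, alpha = 0.05, p_col = "p_fdr")
  expect_identical(counts, printed_significance_counts())
})
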
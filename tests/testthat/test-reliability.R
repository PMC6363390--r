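test_that("correlation estimates and intervals behave at the boundaries", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0, 6.7, 7.1, 8.9)
  p <- correlation_with_ci(x, x, "pearson")
  expect_equal(p$r, 1)
  s <- correlation_with_ci(x, x, "spearman", n_boot = 200)
  expect_equal(s$r, 1)
  expect_equal(correlation_with_ci(x, -x, "pearson")$r, -1)
  expect_error(correlation_with_ci(x, rep(1, 8)), "constant")
  expect_error(correlation_with_ci(x[1:3], x[1:3]), "at least 4")
  # independent noise: small r, interval covering zero
  set.seed(14)
  a <- rnorm(1000); b <- rnorm(1000)
  null <- correlation_with_ci(a, b, "pearson")
  expect_lt(abs(null$r), 0.1)
  expect_lt(null$ci[1], 0)
  expect_gt(null$ci[2], 0)
})

test_that("attenuation correction normalises by the simulation ceiling", {
  expect_equal(corrected_rank_correlation(0.8, 0.8)$corrected_r, 1)
  expect_equal(corrected_rank_correlation(0, 0.9)$corrected_r, 0)
  capped <- corrected_rank_correlation(0.95, 0.9)
  expect_true(capped$capped)
  expect_equal(capped$corrected_r, 1)
  out <- corrected_rank_correlation(0.45, 0.9, observed_ci = c(0.3, 0.6))
  expect_equal(out$corrected_r, 0.5)
  expect_equal(out$corrected_ci, c(0.3, 0.6) / 0.9)
  expect_error(corrected_rank_correlation(0.5, 0), "positive")
})

test_that("the estimation-noise ceiling rises with trials per subject", {
  ceil_for <- function(n_trials) {
    attenuation_ceiling(
      schedule_config("SV", n_trials = n_trials),
      schedule_config("NV", n_trials = n_trials),
      n_subjects = 15, n_rep = 8, seed = 2)$ceiling
  }
  c40 <- ceil_for(40)
  c640 <- ceil_for(640)
  expect_gt(c640, c40)
  expect_gt(c640, 0.9)
  expect_lte(c640, 1)
})

test_that("dependent-correlation tests match their null and an oracle", {
  eq <- compare_dependent_correlations(0.5, 0.5, 0.3, 63)
  expect_equal(eq$statistic, c(0, 0))
  expect_equal(eq$p, c(1, 1))
  expect_error(compare_dependent_correlations(1, 0.5, 0.3, 63), "degenerate")
  # the observed cross-task pattern is significantly unequal at n = 63
  tab <- compare_dependent_correlations(0.79, 0.61, 0.40, 63)
  expect_true(all(tab$p < 0.05))
  # agreement with a subject-resampling permutation oracle: under
  # exchangeability of variables 2 and 3, swapping them per subject gives
  # the null distribution of r12 - r13
  set.seed(4)
  n <- 40
  z <- rnorm(n)
  x1 <- z + rnorm(n, 0, 0.8)
  x2 <- z + rnorm(n, 0, 1.0)
  x3 <- z + rnorm(n, 0, 1.0)
  obs <- cor(x1, x2) - cor(x1, x3)
  perm <- replicate(4000, {
    swap <- runif(n) < 0.5
    x2p <- ifelse(swap, x3, x2)
    x3p <- ifelse(swap, x2, x3)
    cor(x1, x2p) - cor(x1, x3p)
  })
  p_perm <- mean(abs(perm) >= abs(obs))
  p_steiger <- compare_dependent_correlations(cor(x1, x2), cor(x1, x3),
                                              cor(x2, x3), n)$p[1]
  expect_lt(abs(p_perm - p_steiger), 0.1)
})

test_that("bootstrap and permutation tests respond to signal and null", {
  set.seed(6)
  shifted <- rnorm(30, 10, 1)
  bt <- bootstrap_test(shifted, statistic = "mean", n_boot = 2000)
  expect_lt(bt$p, 0.01)
  x <- rnorm(20)
  same <- bootstrap_test(x, x, paired = TRUE, n_boot = 2000)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  y <- x + rnorm(20, 1, 0.2)
  pr <- bootstrap_test(y, x, paired = TRUE, n_boot = 2000)
  expect_lt(pr$p, 0.01)
  two <- bootstrap_test(rnorm(25, 2), rnorm(25, 0), n_boot = 2000)
  expect_lt(two$p, 0.01)
  # determinism given seed
  b1 <- bootstrap_test(x, statistic = "mean", n_boot = 500, seed = 9)
  b2 <- bootstrap_test(x, statistic = "mean", n_boot = 500, seed = 9)
  expect_identical(b1$boot, b2$boot)
  expect_error(bootstrap_test(1), "at least 2")
})

test_that("cross-task regressions recover structure and test factors", {
  set.seed(10)
  n <- 80
  tab <- data.frame(subjid = sprintf("s%02d", 1:n),
                    SV = rnorm(n, -3.5, 1), LV = rnorm(n, -4, 1))
  tab$NV <- 1.3 * tab$SV + 0 * tab$LV + rnorm(n, 0, 0.4)
  fit <- cross_task_regression(tab, "NV", c("SV", "LV"))
  b_sv <- fit$coefficients[fit$coefficients$term == "SV", ]
  b_lv <- fit$coefficients[fit$coefficients$term == "LV", ]
  expect_lt(abs(b_sv$estimate - 1.3), 3 * b_sv$se)
  expect_lt(abs(b_lv$estimate - 0), 3 * b_lv$se)
  expect_gt(fit$r_squared, 0.5)
  # an exact linear response gives R2 = 1
  tab$exact <- 2 * tab$SV - tab$LV + 1
  exact <- suppressWarnings(cross_task_regression(tab, "exact", c("SV", "LV")))
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  # irrelevant factors pass the LR screen at roughly the nominal rate
  rate <- mean(replicate(100, {
    tab$noise <- rnorm(n)
    cross_task_regression(tab, "NV", c("SV", "LV"),
                          extra_factors = "noise")$lr_tests$p < 0.05
  }))
  expect_lt(rate, 0.15)
  tab$dup <- tab$SV
  expect_error(cross_task_regression(tab, "NV", c("SV", "dup")),
               "collinear")
})

test_that("the gap mixed model attributes variance to the right factor", {
  set.seed(12)
  n <- 63
  subj_int <- rnorm(n, 0, 1)
  rows <- do.call(rbind, lapply(1:n, function(s) {
    data.frame(subjid = sprintf("s%02d", s),
               task = c("NV", "SV", "LV"),
               days = c(FALSE, FALSE, TRUE),
               verbal = c(FALSE, TRUE, TRUE))
  }))
  rows$logk <- -3.4 + subj_int[match(rows$subjid, sprintf("s%02d", 1:n))] +
    (-0.52) * rows$days + 0 * rows$verbal + rnorm(nrow(rows), 0, 0.3)
  fit <- gap_variance_mixed_model(rows)
  aic <- fit$aic_table
  expect_lt(aic$lr_p[aic$dropped == "days"], 0.05)
  expect_gt(aic$lr_p[aic$dropped == "verbal"], 0.05)
  b_days <- fit$coefficients[fit$coefficients$term == "daysTRUE", ]
  expect_lt(abs(b_days$estimate - (-0.52)), 3 * b_days$se)
  expect_error(gap_variance_mixed_model(rows[rows$task == "NV", ]),
               "at least 2 tasks")
})

test_that("a vanishing random intercept reduces the mixed model to OLS", {
  set.seed(13)
  n <- 40
  rows <- do.call(rbind, lapply(1:n, function(s) {
    data.frame(subjid = sprintf("s%02d", s),
               task = c("NV", "SV", "LV"),
               days = c(FALSE, FALSE, TRUE),
               verbal = c(FALSE, TRUE, TRUE))
  }))
  rows$logk <- -3 - 0.4 * rows$days + 0.2 * rows$verbal +
    rnorm(nrow(rows), 0, 0.5)
  mm <- suppressMessages(gap_variance_mixed_model(rows))
  ols <- lm(logk ~ days + verbal, data = rows)
  expect_equal(mm$coefficients$estimate, unname(coef(ols)), tolerance = 1e-3)
})

test_that("test-retest splits detect stability and drift", {
  coh <- tiny_cohort()
  tr <- test_retest_summary(coh, split = "half_block")
  expect_gt(tr$pearson_r, 0.5)
  expect_gt(tr$wilcoxon_p, 0.001)
  sess <- test_retest_summary(coh[coh$task == "NV", ], split = "session")
  expect_equal(sess$n, 8)
  # a drifting agent (more patient in the second half of every block)
  set.seed(15)
  drift <- as.data.frame(coh[coh$task == "SV", ])
  half <- integer(nrow(drift))
  for (ix in split(seq_len(nrow(drift)), list(drift$subjid, drift$block))) {
    ord <- ix[order(drift$trial[ix])]
    first <- ord[seq_len(ceiling(length(ord) / 2))]
    half[first] <- 1L
    half[setdiff(ord, first)] <- 2L
  }
  drift$chose_later <- rbinom(nrow(drift), 1,
                              ifelse(half == 1, 0.25, 0.75)) == 1
  res <- test_retest_summary(dd_trials(drift), split = "half_block")
  expect_lt(res$wilcoxon_p, 0.01)
})
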
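# One moderate cohort fit shared by the assertions in this file.
hier_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sched <- lapply(c(NV = "NV", SV = "SV", LV = "LV"), function(t)
        schedule_config(t, n_trials = 100, sessions = 1L))
      pop <- population_config(n_subjects = 12)
      coh <- simulate_cohort(pop, schedules = sched, seed = 77)
      fit <- fit_hierarchical(coh, hier_config(seed = 7))
      cache <<- list(pop = pop, coh = coh, fit = fit)
    }
    cache
  }
})

test_that("the hierarchical fit converges and recovers the population", {
  fx <- hier_fixture()
  fit <- fx$fit
  expect_true(fit$converged)
  expect_lte(fit$diagnostics$max_rhat, fit$config$rhat_limit)
  for (tk in fx$pop$tasks) {
    ps <- posterior_summary(fit, sprintf("mu_logk[%s]", tk))
    expect_lt(abs(ps$mean - fx$pop$mean_logk[[tk]]), 4 * ps$sd)
    # nested intervals: the 95% band contains the 80% band
    expect_lte(ps$intervals["95%", "lower"], ps$intervals["80%", "lower"])
    expect_gte(ps$intervals["95%", "upper"], ps$intervals["80%", "upper"])
  }
})

test_that("subject-level posteriors track the truth and the MLE", {
  fx <- hier_fixture()
  truth <- cohort_truth(fx$coh)
  m <- merge(fx$fit$subject_logk, truth, by = c("subjid", "task"),
             suffixes = c("_post", "_true"))
  expect_gte(cor(m$logk_post, m$logk_true), 0.9)
  mle <- fit_cohort_mle(fx$coh)
  mm <- merge(fx$fit$subject_logk, mle, by = c("subjid", "task"),
              suffixes = c("_post", "_mle"))
  # agreement is expected on well-identified cells; near-one-sided
  # subjects have unbounded MLEs that only the hierarchical prior tames
  ok <- !is.na(mm$logk_mle) & mm$logk_se < 1
  expect_gt(sum(ok), 0.7 * nrow(mm))
  expect_gte(cor(mm$logk_post[ok], mm$logk_mle[ok]), 0.95)
  # subject deviations are softly centred around zero
  b_cols <- grep("^b\\[", colnames(fx$fit$draws), value = TRUE)
  b_means <- colMeans(fx$fit$draws[, b_cols])
  expect_lt(abs(mean(b_means)), 0.1 * sd(b_means))
})

test_that("directional population differences earn large evidence ratios", {
  fx <- hier_fixture()
  er <- evidence_ratio(fx$fit, "mu_logk[NV] > mu_logk[LV]")
  expect_gt(er$log2_evidence_ratio, 1)
})

test_that("Bayesian R2 sits in the band expected for this noise level", {
  fx <- hier_fixture()
  r2 <- bayes_r2(fx$fit, fx$coh, n_draws = 200)
  expect_gt(r2$mean, 0.4)
  expect_lt(r2$mean, 0.8)
  per <- bayes_r2(fx$fit, fx$coh, per_subject = TRUE, n_draws = 100)
  expect_equal(sort(unique(per$subjid)), sort(unique(fx$coh$subjid)))
  expect_true(all(per$r2 >= 0 & per$r2 <= 1))
})

test_that("a homogeneous population yields a small subject-effect SD", {
  sched <- lapply(c(NV = "NV", SV = "SV", LV = "LV"), function(t)
    schedule_config(t, n_trials = 60, sessions = 1L))
  pop <- population_config(n_subjects = 10, sd_logk = c(0, 0, 0))
  coh <- simulate_cohort(pop, schedules = sched, seed = 17)
  fit <- fit_hierarchical(coh, hier_config(seed = 3))
  sd_cols <- grep("^sd_b\\[", colnames(fit$draws), value = TRUE)
  expect_lt(max(colMeans(fit$draws[, sd_cols])), 0.45)
})

test_that("posterior summaries behave on synthetic draws", {
  set.seed(5)
  draws <- cbind("mu_logk[SV]" = rnorm(4000),
                 "mu_logk[NV]" = rnorm(4000) + 1,
                 "sd_b[SV]" = rep(2, 4000),
                 "sd_b[NV]" = rep(2, 4000))
  fake <- make_fake_posterior(draws, tasks = c("SV", "NV"))
  ps <- posterior_summary(fake, "mu_logk[SV]")
  expect_equal(ps$mean, 0, tolerance = 0.1)
  expect_equal(ps$intervals["95%", "lower"], -ps$intervals["95%", "upper"],
               tolerance = 0.15)
  const <- posterior_summary(fake, "sd_b[SV]")
  expect_equal(unname(diff(const$intervals["95%", ])), 0)
  expect_error(posterior_summary(fake, "nonexistent"), "unknown parameter")
})

test_that("evidence ratios follow the draw arithmetic", {
  draws <- cbind("a" = c(rep(1, 75), rep(-1, 25)), "b" = rep(0, 100))
  fake <- make_fake_posterior(draws, tasks = "SV")
  er <- evidence_ratio(fake, "a > b")
  expect_equal(er$posterior_prob, 0.75)
  expect_equal(er$evidence_ratio, 3)
  even <- make_fake_posterior(cbind("a" = c(rep(1, 50), rep(-1, 50)),
                                    "b" = rep(0, 100)), tasks = "SV")
  er0 <- evidence_ratio(even, "a > b")
  expect_equal(er0$log2_evidence_ratio, 0)
  # one-sided saturation is capped at the draw resolution and flagged
  all_over <- make_fake_posterior(cbind("a" = rep(1, 100), "b" = rep(0, 100)),
                                  tasks = "SV")
  erc <- evidence_ratio(all_over, "a > b")
  expect_true(erc$capped)
  expect_lt(erc$evidence_ratio, Inf)
  expect_equal(evidence_ratio(fake, "a > 0.5")$posterior_prob, 0.75)
  expect_error(evidence_ratio(fake, "a + b"), "form")
  # unconverged fits are refused without force
  bad <- make_fake_posterior(draws, tasks = "SV", converged = FALSE)
  expect_error(evidence_ratio(bad, "a > b"), "not converged")
  expect_no_error(evidence_ratio(bad, "a > b", force = TRUE))
})

test_that("k-fold comparisons use pointwise contributions", {
  a <- structure(list(kfold_ic = 1000, elpd = -500,
                      pointwise = rep(-0.5, 1000), k = 10, n = 1000),
                 class = "dd_kfold")
  expect_equal(a$kfold_ic, -2 * a$elpd)
  set.seed(8)
  pw_b <- rep(-0.5, 1000) - rnorm(1000, 0.01, 0.02)
  b <- structure(list(kfold_ic = -2 * sum(pw_b), elpd = sum(pw_b),
                      pointwise = pw_b, k = 10, n = 1000),
                 class = "dd_kfold")
  cmp <- kfold_compare(a, b)
  d <- a$pointwise - pw_b
  expect_equal(cmp$delta_elpd, sum(d))
  expect_equal(cmp$se, 2 * sqrt(1000 * var(d)))
  expect_equal(cmp$delta_kfold_ic, -2 * sum(d))
  expect_equal(cmp$better, "a")
})
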
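test_that("schedules cover the full offer grid with the configured shares", {
  for (task in c("NV", "SV", "LV")) {
    cfg <- schedule_config(task)
    sch <- make_offer_schedule(cfg, seed = 5)
    expect_equal(nrow(unique(sch[, c("later_mag", "later_delay")])), 25)
    comp <- schedule_composition(cfg)
    share <- sum(comp$n_trials[comp$smaller_later]) / sum(comp$n_trials)
    expect_equal(share, if (task == "NV") 0.25 else 0.10)
    # realised share within binomial error of the target
    sl <- mean(sch$later_mag < sch$sooner_mag)
    expect_lt(abs(sl - share), 3 * sqrt(share * (1 - share) / nrow(sch)))
    # one magnitude per block, delays shuffled within
    per_block <- tapply(sch$later_mag, sch$block,
                        function(x) length(unique(x)))
    expect_true(all(per_block == 1))
  }
  expect_identical(make_offer_schedule(schedule_config("SV"), seed = 9),
                   make_offer_schedule(schedule_config("SV"), seed = 9))
  expect_error(schedule_config("SV", n_trials = 10), "distinct offers")
})

test_that("population draws honour means, SDs and correlations", {
  # degenerate SDs collapse every agent onto the population means
  pop0 <- population_config(n_subjects = 5, sd_logk = c(0, 0, 0),
                            sd_log_tau = 0)
  ag0 <- sample_population(pop0, seed = 1)
  for (tk in pop0$tasks) {
    expect_equal(ag0$logk[ag0$task == tk],
                 rep(pop0$mean_logk[[tk]], 5))
    expect_equal(ag0$tau[ag0$task == tk],
                 rep(pop0$mean_tau[[tk]], 5))
  }
  expect_equal(unname(pop0$mean_logk), c(-3.2, -3.49, -3.95))
  # perfectly correlated tasks reuse one subject factor
  R1 <- matrix(1, 3, 3)
  pop1 <- population_config(n_subjects = 40, cross_task_correlation = R1)
  ag1 <- sample_population(pop1, seed = 2)
  z <- sapply(pop1$tasks, function(tk) {
    (ag1$logk[ag1$task == tk] - pop1$mean_logk[[tk]]) / pop1$sd_logk[[tk]]
  })
  expect_equal(z[, 1], z[, 2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(z[, 1], z[, 3], tolerance = 1e-6, ignore_attr = TRUE)
  # sample correlations approach the configured matrix for large n
  pop <- population_config(n_subjects = 4000)
  ag <- sample_population(pop, seed = 3)
  lk <- sapply(pop$tasks, function(tk) ag$logk[ag$task == tk])
  expect_equal(unname(cor(lk)[lower.tri(diag(3))]),
               unname(pop$cross_task_correlation[lower.tri(diag(3))]),
               tolerance = 0.06)
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3)
  expect_error(population_config(cross_task_correlation = bad),
               "semi-definite")
})

test_that("simulated choice rates follow the choice rule", {
  sched <- make_offer_schedule(schedule_config("SV", n_trials = 25,
                                               block_jitter = 0), seed = 1)
  # noiseless limit picks the higher-utility option every time
  agent <- list(subjid = "a", logk = -3, tau = 1e-9, alpha = 1, rho = 1)
  tr <- simulate_choices(agent, sched, "SV", seed = 1)
  u_l <- hyperbolic_utility(tr$later_mag, tr$later_delay, exp(-3))
  expect_equal(tr$chose_later, u_l > 4)
  # an offer engineered to have equal utilities is chosen half the time
  n <- 10000
  eq_sched <- data.frame(session = 1L, block = 1L, trial = seq_len(n),
                         sooner_mag = 4, later_mag = 4 * (1 + exp(-3) * 10),
                         later_delay = 10, delay_unit = "second")
  agent$tau <- 0.8
  tr_eq <- simulate_choices(agent, eq_sched, "SV", seed = 2)
  expect_lt(abs(mean(tr_eq$chose_later) - 0.5), 3 * sqrt(0.25 / n))
  # Monte-Carlo rates converge to the closed-form softmax probability
  one <- data.frame(session = 1L, block = 1L, trial = seq_len(n),
                    sooner_mag = 4, later_mag = 8, later_delay = 14,
                    delay_unit = "second")
  tr_mc <- simulate_choices(agent, one, "SV", seed = 3)
  p_true <- softmax_choice_prob(hyperbolic_utility(8, 14, exp(-3)), 4, 0.8)
  expect_lt(abs(mean(tr_mc$chose_later) - p_true),
            3 * sqrt(p_true * (1 - p_true) / n))
  expect_error(simulate_choices(list(subjid = "a", logk = -3, tau = 0),
                                one, "SV", seed = 1), "tau")
})

test_that("choice probabilities are monotone over the offer grid", {
  mags <- c(1, 2, 5, 8, 10); delays <- c(3, 6.5, 14, 30, 64)
  for (d in delays) {
    p <- softmax_choice_prob(hyperbolic_utility(mags, d, exp(-3)), 4, 0.8)
    expect_true(all(diff(p) > 0))
  }
  for (m in mags) {
    p <- softmax_choice_prob(hyperbolic_utility(m, delays, exp(-3)), 4, 0.8)
    expect_true(all(diff(p) < 0))
  }
})

test_that("cohorts have the study shape and are seed-deterministic", {
  coh <- tiny_cohort()
  counts <- table(coh$subjid, coh$task)
  expect_true(all(counts >= 160))
  expect_setequal(unique(coh$task), c("NV", "SV", "LV"))
  expect_equal(length(unique(coh$subjid)), 8)
  truth <- cohort_truth(coh)
  expect_equal(nrow(truth), 8 * 3)
  coh2 <- simulate_cohort(population_config(n_subjects = 8), seed = 42)
  expect_equal(as.data.frame(coh), as.data.frame(coh2), ignore_attr = TRUE)
  solo <- simulate_cohort(population_config(n_subjects = 1), seed = 1)
  expect_equal(length(unique(solo$subjid)), 1)
})

test_that("day/week control tasks use their native grids", {
  pop <- population_config(n_subjects = 2, tasks = c("DV", "WV"))
  coh <- simulate_cohort(pop, seed = 6)
  expect_setequal(unique(coh$delay_unit[coh$task == "DV"]), "day")
  expect_setequal(unique(coh$delay_unit[coh$task == "WV"]), "week")
  expect_lte(max(coh$later_delay[coh$task == "DV"]), 64)
  expect_lte(max(coh$later_delay[coh$task == "WV"]), 35)
  expect_equal(length(unique(coh$later_delay[coh$task == "WV"])), 5)
})
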
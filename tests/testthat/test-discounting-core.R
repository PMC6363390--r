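test_that("utility families evaluate their closed forms", {
  # zero delay returns face value; kT = 1 halves it for any (V, k)
  expect_equal(hyperbolic_utility(10, 0, 0.123), 10)
  for (k in c(1e-4, 0.05, 3)) {
    expect_equal(hyperbolic_utility(10, 1 / k, k), 5)
    expect_equal(hyperbolic_utility(7.3, 1 / k, k), 7.3 / 2)
  }
  # a subject with log(k) = -3 per second halves 10 coins in ~20 s
  expect_equal(hyperbolic_utility(10, 20, exp(-3)), 5, tolerance = 0.003)
  expect_equal(exponential_utility(8, 0, 0.7), 8)
  expect_equal(exponential_utility(8, 10, 0.1), 8 * exp(-1))
  expect_equal(exponential_utility(10, log(2) / 0.25, 0.25), 5)
  # curvature and scaling enter as (rho V)^alpha before discounting
  expect_equal(hyperbolic_utility(9, 0, 1, alpha = 0.5, rho = 4), 6)
  expect_error(hyperbolic_utility(-1, 0, 1), "magnitude")
  expect_error(exponential_utility(1, -1, 1), "delay")
  expect_error(hyperbolic_utility(1, 1, 0), "discount rate")
})

test_that("choice rules match their closed forms and limits", {
  expect_equal(softmax_choice_prob(5, 4, 1), plogis(1))
  expect_equal(softmax_choice_prob(5, 4, 1), 0.7310586, tolerance = 1e-7)
  expect_equal(softmax_choice_prob(2, 2, 0.3), 0.5)
  expect_equal(softmax_choice_prob(100, 1, 1e9), 0.5, tolerance = 1e-6)
  # overflow-safe for extreme utility gaps
  expect_equal(softmax_choice_prob(1e6, 0, 1), 1)
  expect_equal(matching_choice_prob(4, 1, 1), 0.8)
  expect_equal(matching_choice_prob(3, 3, 0.2), 0.5)
  expect_error(softmax_choice_prob(1, 1, 0), "tau")
  expect_error(matching_choice_prob(-1, 1, 1), "positive")
})

test_that("softmax is shift-invariant and matching is scale-invariant", {
  set.seed(11)
  for (i in 1:200) {
    u_l <- runif(1, 0.1, 20); u_s <- runif(1, 0.1, 20)
    tau <- runif(1, 0.05, 5)
    shift <- runif(1, -50, 50)
    expect_equal(softmax_choice_prob(u_l + shift, u_s + shift, tau),
                 softmax_choice_prob(u_l, u_s, tau), tolerance = 1e-12)
    scale <- exp(runif(1, -4, 4))
    expect_equal(matching_choice_prob(u_l * scale, u_s * scale, tau),
                 matching_choice_prob(u_l, u_s, tau), tolerance = 1e-12)
  }
})

test_that("trial log-likelihood equals a brute-force recomposition", {
  set.seed(7)
  for (spec in standard_model_classes()) {
    tr <- manual_trials(later_mag = runif(100, 0.5, 12),
                        later_delay = runif(100, 1, 64),
                        chose_later = runif(100) < 0.5)
    params <- list(logk = rnorm(1, -3, 1), tau = exp(rnorm(1, 0, 0.5)))
    ll <- trial_loglik(tr, params, spec)
    # independent recomposition, written out by hand
    k <- exp(params$logk)
    disc <- function(V, T) {
      if (spec$utility == "hyperbolic") V / (1 + k * T) else V * exp(-k * T)
    }
    ul <- disc(tr$later_mag, tr$later_delay)
    us <- disc(tr$sooner_mag, 0)
    p <- if (spec$choice_rule == "softmax") {
      exp(ul / params$tau) / (exp(ul / params$tau) + exp(us / params$tau))
    } else {
      ul^(1 / params$tau) / (ul^(1 / params$tau) + us^(1 / params$tau))
    }
    expected <- ifelse(tr$chose_later, log(p), log(1 - p))
    expect_equal(ll, expected, tolerance = 1e-12)
  }
  # P = 0.5 contributes log(0.5) whatever the outcome
  tr <- manual_trials(rep(4 * (1 + exp(-3) * 10), 2), c(10, 10),
                      c(TRUE, FALSE))
  ll <- trial_loglik(tr, list(logk = -3, tau = 1))
  expect_equal(ll, rep(log(0.5), 2), tolerance = 1e-12)
  expect_error(trial_loglik(tr, list(logk = -3)), "missing")
})

test_that("utilities are monotone in magnitude and delay", {
  V <- seq(1, 10, by = 0.5)
  T_grid <- seq(0, 64, by = 4)
  for (f in list(hyperbolic_utility, exponential_utility)) {
    u_v <- f(V, 10, 0.1)
    expect_true(all(diff(u_v) > 0))
    u_t <- f(5, T_grid, 0.1)
    expect_true(all(diff(u_t) < 0))
  }
})

test_that("rate unit conversions shift log(k) by the log unit ratio", {
  expect_equal(log(convert_rate_units(1, "second", "day")), log(86400))
  expect_equal(round(log(convert_rate_units(1, "second", "day")), 2), 11.37)
  expect_equal(log(convert_rate_units(1, "week", "day")), -log(7))
  expect_equal(convert_rate_units(0.5, "day", "day"), 0.5)
  set.seed(3)
  for (i in 1:50) {
    k <- exp(rnorm(1, -3, 2))
    units <- sample(c("second", "day", "week"), 2)
    back <- convert_rate_units(convert_rate_units(k, units[1], units[2]),
                               units[2], units[1])
    expect_equal(back, k, tolerance = 1e-12)
  }
  expect_error(convert_rate_units(1, "second", "fortnight"), "unknown")
})

test_that("magnitude correction doubles k and is not idempotent", {
  expect_equal(magnitude_correction(0.0356), 0.0712)
  expect_equal(magnitude_correction(1), 2)
  expect_equal(magnitude_correction(magnitude_correction(1)), 4)
})

test_that("half-value delay and order-of-magnitude gap match printed values", {
  expect_equal(round(half_value_delay(-3)), 20)
  expect_equal(round(half_value_delay(-4)), 55)
  expect_equal(half_value_delay(0), 1)
  expect_identical(orders_of_magnitude_gap(2548.8, 0.0712), 4L)
  expect_identical(orders_of_magnitude_gap(1, 1), 0L)
  expect_identical(orders_of_magnitude_gap(1000, 1), 3L)
})

test_that("unit-shift predictions give the printed shifts", {
  expect_equal(round(unit_shift_prediction("day", "week"), 2), 1.95)
  expect_equal(round(unit_shift_prediction("second", "day"), 2), 11.37)
  expect_equal(unit_shift_prediction("day", "day"), 0)
  expect_error(unit_shift_prediction("day", "fortnight"), "unknown")
})
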
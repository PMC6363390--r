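#' Hyperbolic utility of a delayed reward
#'
#' The subjective value of `V` coins delivered after delay `T` under
#' hyperbolic discounting with rate `k` (units 1/time, in the delay's units):
#' `U = (rho * V)^alpha / (1 + k * T)`. With `alpha = rho = 1` this is the
#' plain hyperbolic form `V / (1 + k T)`; the delayed reward is worth exactly
#' half its face value when `k * T = 1`.
#'
#' @param V Reward magnitude(s), > 0.
#' @param T_delay Delay(s) in the same time units as `1/k`, >= 0.
#' @param k Discount rate(s), > 0.
#' @param alpha Utility curvature exponent, > 0 (default 1).
#' @param rho Reward scaling factor, > 0 (default 1).
#' @return Numeric vector of utilities.
#' @examples
#' hyperbolic_utility(10, 0, 0.05)        # no delay: face value 10
#' hyperbolic_utility(10, 20, exp(-3))    # ~half value at k*T ~= 1
#' @export
hyperbolic_utility <- function(V, T_delay, k, alpha = 1, rho = 1) {
  check_utility_args(V, T_delay, k, alpha, rho)
  (rho * V)^alpha / (1 + k * T_delay)
}

#' Exponential utility of a delayed reward
#'
#' Standard exponential (constant-hazard) discounting:
#' `U = (rho * V)^alpha * exp(-k * T)`.
#'
#' @inheritParams hyperbolic_utility
#' @return Numeric vector of utilities.
#' @examples
#' exponential_utility(8, 10, 0.1)   # 8 * exp(-1)
#' @export
exponential_utility <- function(V, T_delay, k, alpha = 1, rho = 1) {
  check_utility_args(V, T_delay, k, alpha, rho)
  (rho * V)^alpha * exp(-k * T_delay)
}

check_utility_args <- function(V, T_delay, k, alpha, rho) {
  if (any(V <= 0)) stop("magnitude V must be > 0", call. = FALSE)
  if (any(T_delay < 0)) stop("delay T must be >= 0", call. = FALSE)
  if (any(k <= 0)) stop("discount rate k must be > 0", call. = FALSE)
  if (any(alpha <= 0)) stop("curvature alpha must be > 0", call. = FALSE)
  if (any(rho <= 0)) stop("reward scaling rho must be > 0", call. = FALSE)
  invisible(NULL)
}

#' Softmax probability of choosing the later option
#'
#' Shift-invariant logistic choice rule: `P(later) =
#' exp(U_later/tau) / (exp(U_later/tau) + exp(U_sooner/tau))`, computed
#' overflow-safely as `plogis((U_later - U_sooner)/tau)`. Adding a constant
#' to both utilities leaves the probability unchanged.
#'
#' @param u_later,u_sooner Utilities of the later and sooner options.
#' @param tau Decision noise (softmax temperature), > 0.
#' @return Probability (or vector of probabilities) of choosing later.
#' @examples
#' softmax_choice_prob(5, 4, 1)   # plogis(1)
#' @export
softmax_choice_prob <- function(u_later, u_sooner, tau) {
  if (any(tau <= 0)) stop("decision noise tau must be > 0", call. = FALSE)
  if (any(!is.finite(u_later)) || any(!is.finite(u_sooner))) {
    stop("utilities must be finite", call. = FALSE)
  }
  stats::plogis((u_later - u_sooner) / tau)
}

#' Matching (Luce power) probability of choosing the later option
#'
#' Scale-invariant matching rule: `P(later) =
#' U_later^(1/tau) / (U_later^(1/tau) + U_sooner^(1/tau))`, computed on the
#' log scale so large exponents do not overflow. Multiplying both utilities
#' by any positive constant leaves the probability unchanged; with `tau = 1`
#' this is the plain Luce ratio.
#'
#' @inheritParams softmax_choice_prob
#' @return Probability (or vector of probabilities) of choosing later.
#' @examples
#' matching_choice_prob(4, 1, 1)   # 4 / (4 + 1) = 0.8
#' @export
matching_choice_prob <- function(u_later, u_sooner, tau) {
  if (any(tau <= 0)) stop("decision noise tau must be > 0", call. = FALSE)
  if (any(u_later <= 0) || any(u_sooner <= 0)) {
    stop("matching rule requires strictly positive utilities", call. = FALSE)
  }
  stats::plogis((log(u_later) - log(u_sooner)) / tau)
}

# Vectorised P(choose later) for a trial table under a model class and
# per-trial parameters (recycled as needed). Internal workhorse shared by
# the likelihood, the simulator and the delta-utility computation.
choice_prob_later <- function(later_mag, later_delay, sooner_mag, sooner_delay,
                              logk, tau, alpha = 1, rho = 1, spec = model_spec()) {
  k <- exp(logk)
  ufun <- switch(spec$utility,
                 hyperbolic = hyperbolic_utility,
                 exponential = exponential_utility)
  u_l <- ufun(later_mag, later_delay, k, alpha, rho)
  u_s <- ufun(sooner_mag, sooner_delay, k, alpha, rho)
  switch(spec$choice_rule,
         softmax = softmax_choice_prob(u_l, u_s, tau),
         matching = matching_choice_prob(u_l, u_s, tau))
}

# Clip probabilities away from 0/1 before taking logs inside likelihoods.
DD_PROB_EPS <- 1e-12
clip_prob <- function(p) pmin(pmax(p, DD_PROB_EPS), 1 - DD_PROB_EPS)

#' Per-trial Bernoulli log-likelihood under a discounting model
#'
#' Composes the utility family and the choice rule of `spec` with the
#' subject parameters in `params`, and returns the log-likelihood
#' contribution of each trial's observed choice. Probabilities are clipped
#' to `[1e-12, 1 - 1e-12]` before taking logs.
#'
#' @param trials A trial table (see [read_trials()]) or any data frame with
#'   columns `later_mag`, `later_delay`, `sooner_mag`, `chose_later`.
#' @param params Named list or vector with `logk`, `tau`, and (if the model
#'   requires them) `alpha` and `rho`.
#' @param spec A [model_spec()].
#' @return Numeric vector of per-trial log-likelihood contributions; sum it
#'   to obtain the subject log-likelihood.
#' @examples
#' tr <- data.frame(later_mag = 10, later_delay = 30, sooner_mag = 4,
#'                  chose_later = TRUE)
#' trial_loglik(tr, list(logk = -3, tau = 1))
#' @export
trial_loglik <- function(trials, params, spec = model_spec()) {
  params <- as.list(params)
  required <- c("logk", "tau",
                if (spec$curvature) "alpha" else NULL,
                if (spec$reward_scaling) "rho" else NULL)
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    stop("params missing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- choice_prob_later(
    later_mag = trials$later_mag,
    later_delay = trials$later_delay,
    sooner_mag = trials$sooner_mag,
    sooner_delay = 0,
    logk = params$logk, tau = params$tau,
    alpha = if (spec$curvature) params$alpha else 1,
    rho = if (spec$reward_scaling) params$rho else 1,
    spec = spec
  )
  p <- clip_prob(p)
  ifelse(trials$chose_later, log(p), log1p(-p))
}

#' Convert a discount rate between time units
#'
#' A discount rate has units 1/time, so re-expressing it in a larger time
#' unit multiplies it by the unit ratio (e.g. per-second to per-day
#' multiplies by 86400, shifting log(k) by log(86400) = 11.37).
#'
#' @param k Discount rate(s), > 0.
#' @param from,to Units among `"second"`, `"day"`, `"week"`.
#' @return `k` expressed per `to`-unit.
#' @examples
#' convert_rate_units(exp(-3), "second", "day")
#' log(convert_rate_units(1, "second", "day"))  # 11.37
#' @export
convert_rate_units <- function(k, from, to) {
  ratio <- unit_seconds(to) / unit_seconds(from)
  k * ratio
}

unit_seconds <- function(unit) {
  cs <- dd_constants()
  sec <- c(second = 1,
           day = cs$seconds_per_day,
           week = cs$seconds_per_day * cs$days_per_week)
  if (any(!unit %in% names(sec))) {
    stop("unknown delay unit(s): ",
         paste(setdiff(unit, names(sec)), collapse = ", "), call. = FALSE)
  }
  unname(sec[unit])
}

#' Magnitude-effect correction of a discount rate
#'
#' Small rewards are discounted more steeply than large ones. When comparing
#' a rate measured at a large-stake reward scale (the long-horizon task)
#' against rates measured at small stakes (the short-horizon tasks), the
#' cited adjustment multiplies k by a factor of 2. The correction is a
#' one-step factor, not idempotent: applying it twice multiplies by 4.
#'
#' @param k Discount rate(s), > 0.
#' @param direction Currently only `"long_to_short_rewards"`.
#' @return Corrected rate(s).
#' @examples
#' magnitude_correction(0.0356)   # 0.0712
#' @export
magnitude_correction <- function(k, direction = "long_to_short_rewards") {
  direction <- match.arg(direction, "long_to_short_rewards")
  if (any(k <= 0)) stop("k must be > 0", call. = FALSE)
  k * dd_constants()$magnitude_factor
}

#' Delay at which a reward loses half its value
#'
#' Under hyperbolic discounting `U = V / (1 + kT)` equals `V/2` exactly when
#' `k T = 1`, so the half-value delay is `1/k = exp(-log(k))`, in the units
#' of `1/k`.
#'
#' @param logk Natural log of the discount rate.
#' @return Delay in the rate's time units.
#' @examples
#' half_value_delay(-3)   # ~20 (e.g. seconds if k is per-second)
#' @export
half_value_delay <- function(logk) {
  if (any(!is.finite(logk))) stop("logk must be finite", call. = FALSE)
  exp(-logk)
}

#' Order-of-magnitude gap between two discount rates
#'
#' `floor(log10(k_a / k_b))` for rates expressed in the same units.
#'
#' @param k_a,k_b Discount rates, > 0, in the same units.
#' @return Integer number of decades.
#' @examples
#' orders_of_magnitude_gap(2548.8, 0.0712)   # 4
#' @export
orders_of_magnitude_gap <- function(k_a, k_b) {
  if (any(k_a <= 0) || any(k_b <= 0)) stop("rates must be > 0", call. = FALSE)
  as.integer(floor(log10(k_a / k_b)))
}

#' Predicted log(k) shift if subjects ignored delay units
#'
#' If choices depended only on the printed number of time units, a task in
#' larger units would yield a log discount rate larger by the log of the
#' unit ratio: log(7) = 1.95 for days vs. weeks, log(86400) = 11.37 for
#' seconds vs. days.
#'
#' @param u_from,u_to Units among `"second"`, `"day"`, `"week"` (the shift is
#'   for moving from `u_from`-denominated to `u_to`-denominated offers).
#' @return Predicted shift in log(k) (natural log of the unit ratio).
#' @examples
#' unit_shift_prediction("day", "week")      # log(7)  = 1.95
#' unit_shift_prediction("second", "day")    # log(86400) = 11.37
#' @export
unit_shift_prediction <- function(u_from, u_to) {
  log(unit_seconds(u_to) / unit_seconds(u_from))
}
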
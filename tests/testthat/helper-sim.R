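# Shared fixtures, all generated in code.

# Minimal posterior object with known draws, for testing the operations
# that only consume the draws matrix (summaries, evidence ratios,
# shift/scale comparisons).
make_fake_posterior <- function(draws, tasks, converged = TRUE) {
  stopifnot(is.matrix(draws), !is.null(colnames(draws)))
  structure(list(
    draws = draws, mcmc = NULL, subject_logk = NULL,
    tasks = tasks, subjects = character(), horizons = character(),
    config = hier_config(seed = 1),
    diagnostics = list(rhat = c(dummy = 1), max_rhat = 1,
                       n_eff = c(dummy = nrow(draws)),
                       min_n_eff = nrow(draws)),
    converged = converged, n_obs = 0L
  ), class = "dd_posterior")
}

# A small three-task cohort used by several files (8 subjects, default
# schedules). Built once per test run.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(population_config(n_subjects = 8), seed = 42)
    }
    cache
  }
})

# Adaptation records simulated from the mixed logistic model itself:
# per-subject random intercept and utility slope, optional early-by-task
# interaction on the logit scale (the adaptation effect).
simulate_adaptation_records <- function(n_subjects, n_trials,
                                        beta_sv_early = 0,
                                        beta_sv = 0.3, beta_sv_du = 0.2,
                                        early_max = 4, seed = 1) {
  set.seed(seed)
  rows <- vector("list", n_subjects * 2)
  i <- 0
  for (s in seq_len(n_subjects)) {
    b0 <- rnorm(1, 0, 0.5)
    b1 <- exp(rnorm(1, 0, 0.2))
    for (task in c("SV", "LV")) {
      du <- runif(n_trials, -3, 4)
      early <- seq_len(n_trials) <= early_max
      sv <- task == "SV"
      eta <- b0 + b1 * du + beta_sv_du * du * sv + beta_sv * sv +
        beta_sv_early * early * sv
      i <- i + 1
      rows[[i]] <- data.frame(
        subjid = sprintf("s%03d", s), task = task,
        trial = seq_len(n_trials), early = early, delta_u = du,
        chose_later = rbinom(n_trials, 1, plogis(eta)) == 1)
    }
  }
  do.call(rbind, rows)
}

# One-subject trial table with hand-set offers (for likelihood oracles).
manual_trials <- function(later_mag, later_delay, chose_later,
                          task = "SV", sooner_mag = 4) {
  n <- length(later_mag)
  dd_trials(data.frame(
    subjid = "s01", task = task, session = 1L, block = 1L,
    trial = seq_len(n), sooner_mag = sooner_mag, later_mag = later_mag,
    later_delay = later_delay, delay_unit = task_delay_unit(task),
    chose_later = chose_later))
}
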
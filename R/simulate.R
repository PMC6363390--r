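# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All simulator entry points funnel through this
# so a single integer seed fixes every draw without touching global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

DD_DEFAULT_DELAYS <- list(
  NV = c(3, 6.5, 14, 30, 64),
  SV = c(3, 6.5, 14, 30, 64),
  LV = c(3, 6.5, 14, 30, 64),
  DV = c(1, 3, 8, 25, 64),
  WV = c(1, 3, 7, 16, 35)
)

DD_DEFAULT_NTRIALS <- c(NV = 200, SV = 170, LV = 170, DV = 200, WV = 200)
DD_DEFAULT_SL_SHARE <- c(NV = 0.25, SV = 0.10, LV = 0.10, DV = 0.10, WV = 0.10)
DD_DEFAULT_SESSIONS <- list(NV = 1:3, SV = 4:5, LV = 4:5, DV = 1L, WV = 1L)

#' Configure an offer schedule for one task
#'
#' Offers are structured in blocks; each block presents one later-reward
#' magnitude at randomly ordered delays, and block lengths are jittered.
#' Later offers whose magnitude falls below the fixed sooner magnitude
#' ("smaller-later" catch offers) receive a configured share of trials,
#' split equally among the smaller magnitudes; all larger-later offers are
#' equally likely.
#'
#' @param task Task token (`NV`, `SV`, `LV`, `DV`, `WV`).
#' @param delays Later-option delays in the task's native units
#'   (default: 3, 6.5, 14, 30, 64 for NV/SV/LV; day and week grids spanning
#'   1--64 days and 1--35 weeks for DV/WV).
#' @param magnitudes Later-option magnitudes in coins (default 1, 2, 5, 8, 10).
#' @param sooner_magnitude Fixed immediate option, in coins (default 4).
#' @param n_trials Target number of trials (defaults: 200 NV/DV/WV, 170
#'   SV/LV; realised totals vary by the block jitter).
#' @param smaller_later_share Probability mass on dominated later offers
#'   (default 0.25 for NV, 0.10 for verbal tasks).
#' @param block_jitter Half-width of the uniform block-length jitter in
#'   trials (default 1; 0 disables jitter).
#' @param sessions Session labels over which blocks are spread.
#' @return A `dd_schedule_config` list.
#' @export
schedule_config <- function(task,
                            delays = NULL,
                            magnitudes = c(1, 2, 5, 8, 10),
                            sooner_magnitude = 4,
                            n_trials = NULL,
                            smaller_later_share = NULL,
                            block_jitter = 1,
                            sessions = NULL) {
  task <- match.arg(task, DD_TASKS)
  delays <- delays %||% DD_DEFAULT_DELAYS[[task]]
  n_trials <- n_trials %||% unname(DD_DEFAULT_NTRIALS[task])
  smaller_later_share <- smaller_later_share %||% unname(DD_DEFAULT_SL_SHARE[task])
  sessions <- sessions %||% DD_DEFAULT_SESSIONS[[task]]
  stopifnot(length(delays) > 0, all(delays > 0),
            length(magnitudes) > 0, all(magnitudes > 0),
            sooner_magnitude > 0,
            smaller_later_share >= 0, smaller_later_share <= 1,
            block_jitter >= 0)
  if (n_trials < length(delays) * length(magnitudes)) {
    stop("n_trials must be at least the number of distinct offers",
         call. = FALSE)
  }
  structure(list(
    task = task, delays = delays, magnitudes = magnitudes,
    sooner_magnitude = sooner_magnitude, n_trials = n_trials,
    smaller_later_share = smaller_later_share,
    block_jitter = block_jitter,
    sessions = as.integer(sessions),
    delay_unit = task_delay_unit(task)
  ), class = "dd_schedule_config")
}

#' Deterministic trial allocation of a schedule
#'
#' Splits the configured number of trials across later-reward magnitudes:
#' the smaller-later share goes to magnitudes below the sooner magnitude
#' (split equally among them), the remainder equally to the larger
#' magnitudes, using largest-remainder rounding. This is the composition
#' around which block lengths are jittered.
#'
#' @param config A [schedule_config()].
#' @return Data frame with columns `magnitude`, `n_trials`, `smaller_later`.
#' @export
schedule_composition <- function(config) {
  stopifnot(inherits(config, "dd_schedule_config"))
  mags <- config$magnitudes
  small <- mags < config$sooner_magnitude
  n <- config$n_trials
  ideal <- numeric(length(mags))
  if (any(small)) {
    ideal[small] <- n * config$smaller_later_share / sum(small)
    ideal[!small] <- n * (1 - config$smaller_later_share) / sum(!small)
  } else {
    ideal[] <- n / length(mags)
  }
  counts <- floor(ideal)
  remainder <- n - sum(counts)
  if (remainder > 0) {
    extra <- order(ideal - counts, decreasing = TRUE)[seq_len(remainder)]
    counts[extra] <- counts[extra] + 1
  }
  data.frame(magnitude = mags, n_trials = as.integer(counts),
             smaller_later = small)
}

#' Generate a blocked offer schedule
#'
#' Builds the ordered list of offers for one task: one block per later
#' magnitude with length jittered uniformly in `base +/- block_jitter`
#' trials, blocks in random order spread over the configured sessions, and
#' delays cycled in random order within each block (so every distinct offer
#' appears whenever the block is at least as long as the delay grid).
#'
#' @param config A [schedule_config()].
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return Data frame with columns `session`, `block`, `trial`,
#'   `sooner_mag`, `later_mag`, `later_delay`, `delay_unit`.
#' @export
make_offer_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "dd_schedule_config"))
  with_seed(seed, {
    comp <- schedule_composition(config)
    n_blocks <- nrow(comp)
    jit <- if (config$block_jitter > 0) {
      sample(seq(-config$block_jitter, config$block_jitter), n_blocks,
             replace = TRUE)
    } else rep(0L, n_blocks)
    lengths <- pmax(comp$n_trials + jit, length(config$delays))
    order_blocks <- sample.int(n_blocks)
    rows <- vector("list", n_blocks)
    for (bi in seq_len(n_blocks)) {
      b <- order_blocks[bi]
      len <- lengths[b]
      delays <- rep(config$delays, length.out = len)[sample.int(len)]
      rows[[bi]] <- data.frame(
        block = bi,
        sooner_mag = config$sooner_magnitude,
        later_mag = comp$magnitude[b],
        later_delay = delays
      )
    }
    out <- do.call(rbind, rows)
    out$trial <- seq_len(nrow(out))
    # spread blocks over sessions as evenly as the block grid allows
    sess <- config$sessions
    block_session <- sess[ceiling(seq_len(n_blocks) / (n_blocks / length(sess)))]
    out$session <- block_session[out$block]
    out$delay_unit <- config$delay_unit
    out[, c("session", "block", "trial", "sooner_mag", "later_mag",
            "later_delay", "delay_unit")]
  })
}

#' Configure a simulated population of agents
#'
#' Subject-level log discount factors are drawn jointly normal across tasks
#' with configurable means, SDs and cross-task correlation; decision noise
#' has per-task population levels with a single shared per-subject
#' deviation (on the log scale); reward scaling has per-horizon (short =
#' seconds tasks, long = day/week tasks) levels, degenerate at 1 by
#' default.
#'
#' @param n_subjects Number of agents (default 63).
#' @param tasks Tasks simulated (default `NV`, `SV`, `LV`).
#' @param mean_logk Named per-task means of log(k) in the task's native
#'   units (defaults -3.2 NV, -3.49 SV, -3.95 LV; DV/WV default -3.95).
#' @param sd_logk Named per-task SDs of log(k) across subjects.
#' @param cross_task_correlation Correlation matrix of subject-level log(k)
#'   deviations, in `tasks` order (defaults 0.8 NV-SV, 0.6 SV-LV, 0.4
#'   NV-LV).
#' @param mean_tau Named per-task population decision noise (geometric
#'   means; defaults 1.5 NV, 0.8 elsewhere).
#' @param sd_log_tau SD of the shared per-subject log-noise deviation.
#' @param mean_rho Named per-horizon reward-scaling levels (default 1).
#' @param sd_log_rho Named per-horizon SDs of subject log reward-scaling
#'   deviations (default 0: no heterogeneity).
#' @return A `dd_population_config` list.
#' @export
population_config <- function(n_subjects = 63,
                              tasks = c("NV", "SV", "LV"),
                              mean_logk = NULL,
                              sd_logk = NULL,
                              cross_task_correlation = NULL,
                              mean_tau = NULL,
                              sd_log_tau = 0.3,
                              mean_rho = c(short = 1, long = 1),
                              sd_log_rho = c(short = 0, long = 0)) {
  tasks <- match.arg(tasks, DD_TASKS, several.ok = TRUE)
  nt <- length(tasks)
  defaults_mu <- c(NV = -3.2, SV = -3.49, LV = -3.95, DV = -3.95, WV = -3.95)
  defaults_sd <- c(NV = 1.1, SV = 0.8, LV = 1.2, DV = 1.2, WV = 1.2)
  defaults_tau <- c(NV = 1.5, SV = 0.8, LV = 0.8, DV = 0.8, WV = 0.8)
  mean_logk <- fill_task_map(mean_logk, tasks, defaults_mu)
  sd_logk <- fill_task_map(sd_logk, tasks, defaults_sd)
  mean_tau <- fill_task_map(mean_tau, tasks, defaults_tau)
  if (is.null(cross_task_correlation)) {
    cross_task_correlation <- default_cross_task_correlation(tasks)
  }
  R <- as.matrix(cross_task_correlation)
  if (!isTRUE(all.equal(R, t(R))) || !isTRUE(all.equal(unname(diag(R)), rep(1, nt)))) {
    stop("cross_task_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    stop("cross_task_correlation must be positive semi-definite",
         call. = FALSE)
  }
  mean_rho <- fill_task_map(mean_rho, c("short", "long"),
                            c(short = 1, long = 1))
  sd_log_rho <- fill_task_map(sd_log_rho, c("short", "long"),
                              c(short = 0, long = 0))
  stopifnot(all(sd_logk >= 0), all(mean_tau > 0), sd_log_tau >= 0,
            all(mean_rho > 0), all(sd_log_rho >= 0))
  structure(list(
    n_subjects = as.integer(n_subjects), tasks = tasks,
    mean_logk = mean_logk, sd_logk = sd_logk,
    cross_task_correlation = R,
    mean_tau = mean_tau, sd_log_tau = sd_log_tau,
    mean_rho = mean_rho, sd_log_rho = sd_log_rho
  ), class = "dd_population_config")
}

fill_task_map <- function(x, tasks, defaults) {
  if (is.null(x)) return(defaults[tasks])
  if (is.null(names(x))) {
    stopifnot(length(x) == length(tasks))
    names(x) <- tasks
    return(x)
  }
  out <- defaults[tasks]
  out[intersect(names(x), tasks)] <- x[intersect(names(x), tasks)]
  out
}

# Pairwise correlation pattern emulating the observed cross-task structure:
# strongest between the two short tasks, weakest across both the horizon
# and modality gaps.
default_cross_task_correlation <- function(tasks) {
  base <- c("NV.SV" = 0.8, "SV.LV" = 0.6, "NV.LV" = 0.4,
            "DV.WV" = 0.9,
            "NV.DV" = 0.4, "NV.WV" = 0.4, "SV.DV" = 0.6, "SV.WV" = 0.6,
            "LV.DV" = 0.8, "LV.WV" = 0.8)
  nt <- length(tasks)
  R <- diag(nt)
  dimnames(R) <- list(tasks, tasks)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    key1 <- paste(tasks[i], tasks[j], sep = ".")
    key2 <- paste(tasks[j], tasks[i], sep = ".")
    r <- if (key1 %in% names(base)) base[[key1]] else base[[key2]] %||% 0.5
    R[i, j] <- r
  }
  R
}

task_horizon <- function(task) {
  ifelse(task_delay_unit(task) == "second", "short", "long")
}

#' Draw a population of agents
#'
#' Per-task subject deviations of log(k) are drawn jointly normal with the
#' configured cross-task correlation and added to the population means;
#' decision noise and reward scaling are drawn log-normally. Deterministic
#' given the seed.
#'
#' @param config A [population_config()].
#' @param seed Integer seed.
#' @return Data frame (long, one row per subject-task) with columns
#'   `subjid`, `task`, `logk`, `tau`, `alpha`, `rho`.
#' @export
sample_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "dd_population_config"))
  with_seed(seed, {
    ns <- config$n_subjects
    tasks <- config$tasks
    nt <- length(tasks)
    # correlated standard normal deviations via the Cholesky root
    # (eigen fallback when the matrix is PSD but singular)
    R <- config$cross_task_correlation
    L <- tryCatch(t(chol(R)), error = function(e) {
      e_dec <- eigen(R, symmetric = TRUE)
      e_dec$vectors %*% diag(sqrt(pmax(e_dec$values, 0)), nt)
    })
    z <- matrix(stats::rnorm(ns * nt), ns, nt) %*% t(L)
    logk <- sweep(z * rep(config$sd_logk, each = ns), 2,
                  config$mean_logk, "+")
    u <- stats::rnorm(ns, 0, config$sd_log_tau)
    horizons <- task_horizon(tasks)
    v <- matrix(
      c(stats::rnorm(ns, 0, config$sd_log_rho[["short"]]),
        stats::rnorm(ns, 0, config$sd_log_rho[["long"]])),
      nrow = ns, dimnames = list(NULL, c("short", "long")))
    subjid <- sprintf("s%02d", seq_len(ns))
    out <- do.call(rbind, lapply(seq_len(nt), function(t) {
      data.frame(
        subjid = subjid, task = tasks[t],
        logk = logk[, t],
        tau = exp(log(config$mean_tau[[tasks[t]]]) + u),
        alpha = 1,
        rho = exp(log(config$mean_rho[[horizons[t]]]) + v[, horizons[t]])
      )
    }))
    row.names(out) <- NULL
    out
  })
}

#' Simulate one agent's choices on an offer schedule
#'
#' Each trial's `chose_later` is a Bernoulli draw with probability given by
#' the model's choice rule applied to the agent's utilities.
#'
#' @param agent One-row data frame (or list) with `subjid`, `logk`, `tau`,
#'   `alpha`, `rho`.
#' @param schedule Offer schedule from [make_offer_schedule()].
#' @param task Task token for the records.
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return A `dd_trials` table for this agent and task.
#' @export
simulate_choices <- function(agent, schedule, task, spec = model_spec(),
                             seed = NULL) {
  agent <- as.list(agent)
  with_seed(seed, {
    p <- choice_prob_later(
      later_mag = schedule$later_mag,
      later_delay = schedule$later_delay,
      sooner_mag = schedule$sooner_mag,
      sooner_delay = 0,
      logk = agent$logk, tau = agent$tau,
      alpha = agent$alpha %||% 1, rho = agent$rho %||% 1,
      spec = spec
    )
    chose <- stats::rbinom(nrow(schedule), 1, p) == 1
    dd_trials(data.frame(
      subjid = agent$subjid, task = task,
      session = schedule$session, block = schedule$block,
      trial = schedule$trial,
      sooner_mag = schedule$sooner_mag,
      later_mag = schedule$later_mag,
      later_delay = schedule$later_delay,
      delay_unit = schedule$delay_unit,
      chose_later = chose
    ))
  })
}

#' Simulate a full cohort
#'
#' Composes [sample_population()], [make_offer_schedule()] (a fresh random
#' schedule per subject and task) and [simulate_choices()] into a
#' study-shaped dataset. The generating agent parameters are attached as
#' the `truth` attribute.
#'
#' @param pop A [population_config()].
#' @param schedules Named list of [schedule_config()]s, one per task
#'   (defaults built from each task's packaged defaults).
#' @param spec A [model_spec()] used as the generating model.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A `dd_trials` table with attributes `truth` (agent parameters)
#'   and a provenance record of the generating configuration.
#' @export
simulate_cohort <- function(pop = population_config(),
                            schedules = NULL,
                            spec = model_spec(),
                            seed = 1) {
  stopifnot(inherits(pop, "dd_population_config"))
  if (is.null(schedules)) {
    schedules <- lapply(pop$tasks, schedule_config)
    names(schedules) <- pop$tasks
  }
  missing_sched <- setdiff(pop$tasks, names(schedules))
  if (length(missing_sched) > 0) {
    stop("no schedule config for task(s): ",
         paste(missing_sched, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    agents <- sample_population(pop, seed = NULL)
    pieces <- vector("list", nrow(agents))
    for (i in seq_len(nrow(agents))) {
      a <- agents[i, ]
      sched <- make_offer_schedule(schedules[[a$task]], seed = NULL)
      pieces[[i]] <- simulate_choices(a, sched, task = a$task, spec = spec,
                                      seed = NULL)
    }
    out <- dd_trials(do.call(rbind, lapply(pieces, as.data.frame)))
    out <- add_provenance(out, list(
      filter = "simulated",
      n_subjects = pop$n_subjects, tasks = pop$tasks, seed = seed,
      model = paste(spec$utility, spec$choice_rule, sep = "-")))
    attr(out, "truth") <- agents
    out
  })
}

#' Generating agent parameters of a simulated cohort
#'
#' @param trials A cohort from [simulate_cohort()].
#' @return The agent-parameter data frame, or `NULL` for real data.
#' @export
cohort_truth <- function(trials) {
  attr(trials, "truth")
}
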
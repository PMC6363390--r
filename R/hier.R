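#' Configure the hierarchical softmax-hyperbolic model
#'
#' The model mirrors a nonlinear mixed-effects formulation: each choice is
#' Bernoulli with `P(later) = inv_logit((U_later - U_sooner) / tau)`,
#' `U = V / (1 + exp(logk) * T)` in the task's native time units;
#' `logk` has a population level per task plus correlated per-subject
#' deviations per task, and `log(tau)` has a population level per task plus
#' a single per-subject deviation. The optional reward-scaling expansion
#' multiplies both magnitudes by `rho = exp(log rho)` with one level per
#' time-horizon (short = seconds tasks, long = day/week tasks), each with
#' per-subject deviations.
#'
#' Priors: Normal(-3, 3) on population logk; Normal(0, 1) on population
#' log tau; half-Normal(0, 1) on the subject log-tau SD; inverse-Wishart
#' (identity scale, ntasks + 1 df) on the covariance of the subject logk
#' deviations (giving marginally uniform correlations); Normal(0, 0.5) on
#' population log rho and half-Normal(0, 0.5) on its subject SDs, centring
#' the expansion on rho = 1.
#'
#' @param tasks Tasks to include (default: all tasks present in the data).
#' @param reward_scaling Include the per-horizon reward-scaling expansion.
#' @param chains,adapt,burn,draws,thin MCMC settings (defaults 3 chains,
#'   600 adaptation, 800 burn-in, 1200 kept draws per chain).
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @param rhat_limit Convergence gate on split-R-hat of population
#'   parameters (default 1.05); downstream operations refuse fits above it.
#' @return A `dd_hier_config` list.
#' @export
hier_config <- function(tasks = NULL, reward_scaling = FALSE,
                        chains = 3, adapt = 600, burn = 800,
                        draws = 1200, thin = 1, seed = 1,
                        rhat_limit = 1.05) {
  stopifnot(chains >= 2, adapt > 0, burn >= 0, draws > 0, thin >= 1)
  structure(list(tasks = tasks, reward_scaling = reward_scaling,
                 chains = as.integer(chains), adapt = as.integer(adapt),
                 burn = as.integer(burn), draws = as.integer(draws),
                 thin = as.integer(thin), seed = as.integer(seed),
                 rhat_limit = rhat_limit),
            class = "dd_hier_config")
}

build_hier_model_string <- function(n_tasks, reward_scaling, n_horizons) {
  # Subject-level logk is sampled centred on the population mean
  # (hierarchical centring): the population-mean update is then
  # near-conjugate and the Gibbs chain mixes an order of magnitude faster
  # than with zero-centred deviations. b = lk - mu is derived for output.
  rho_num <- if (reward_scaling) "rho_t[j] * " else ""
  lik <- sprintf("
  for (j in 1:N) {
    %sul[j] <- (%slater_mag[j]) / (1 + exp(lk[subj[j], task[j]]) * delay[j])
    us[j] <- %ssooner_mag[j]
    p[j] <- ilogit((ul[j] - us[j]) / exp(mu_logtau[task[j]] + u[subj[j]]))
    y[j] ~ dbin(p[j], n[j])
  }",
  if (reward_scaling) "rho_t[j] <- exp(lrho[subj[j], hor[j]])\n    " else "",
  rho_num, rho_num)
  subj_b <- if (n_tasks >= 2) "
  for (s in 1:S) {
    lk[s, 1:T] ~ dmnorm(mu_logk[1:T], Omega[1:T, 1:T])
    u[s] ~ dnorm(0, prec_u)
    for (t in 1:T) { b[s, t] <- lk[s, t] - mu_logk[t] }
  }
  Omega[1:T, 1:T] ~ dwish(Rw[1:T, 1:T], wish_df)
  Sigma[1:T, 1:T] <- inverse(Omega[1:T, 1:T])
  for (t in 1:T) { sd_b[t] <- sqrt(Sigma[t, t]) }
  for (t1 in 1:T) { for (t2 in 1:T) {
    cor_b[t1, t2] <- Sigma[t1, t2] / (sd_b[t1] * sd_b[t2])
  } }" else "
  for (s in 1:S) {
    lk[s, 1] ~ dnorm(mu_logk[1], prec_b)
    u[s] ~ dnorm(0, prec_u)
    b[s, 1] <- lk[s, 1] - mu_logk[1]
  }
  prec_b <- 1 / (sd_b[1] * sd_b[1])
  sd_b[1] ~ dnorm(0, 0.25) T(0,)"
  pop <- "
  for (t in 1:T) {
    mu_logk[t] ~ dnorm(-3, 0.1111)
    mu_logtau[t] ~ dnorm(0, 1)
  }
  prec_u <- 1 / (sd_u * sd_u)
  sd_u ~ dnorm(0, 1) T(0,)"
  rho <- if (reward_scaling) sprintf("
  for (h in 1:%d) {
    mu_logrho[h] ~ dnorm(0, 4)
    sd_v[h] ~ dnorm(0, 4) T(0,)
    prec_v[h] <- 1 / (sd_v[h] * sd_v[h])
    for (s in 1:S) {
      lrho[s, h] ~ dnorm(mu_logrho[h], prec_v[h])
      v[s, h] <- lrho[s, h] - mu_logrho[h]
    }
  }", n_horizons) else ""
  paste0("model {", lik, subj_b, pop, rho, "\n}")
}

#' Fit the Bayesian hierarchical discounting model
#'
#' Aggregates trials to binomial counts per subject, task and distinct
#' offer, and samples the posterior by Gibbs/slice sampling through
#' 'rjags'. Split-R-hat and effective sample sizes are computed for all
#' population-level parameters; the fit is flagged unconverged if any
#' R-hat exceeds the configured limit, in which case downstream operations
#' refuse it (override with `force = TRUE` where offered).
#'
#' @param trials A prepared trial table.
#' @param config A [hier_config()].
#' @return A `dd_posterior` object: `draws` (matrix of merged posterior
#'   draws with human-readable column names), `mcmc` (per-chain
#'   population-parameter draws), `subject_logk` (per subject-task
#'   posterior mean and SD of logk), `diagnostics`, `converged`, `tasks`,
#'   `config`.
#' @export
fit_hierarchical <- function(trials, config = hier_config()) {
  stopifnot(inherits(config, "dd_hier_config"))
  tasks <- config$tasks %||% sort(unique(trials$task))
  trials <- trials[trials$task %in% tasks, , drop = FALSE]
  if (nrow(trials) == 0) stop("no trials for the requested tasks", call. = FALSE)
  df <- as.data.frame(trials)
  agg <- stats::aggregate(
    cbind(y = df$chose_later, n = 1L) ~ subjid + task + later_mag +
      later_delay + sooner_mag,
    data = df, FUN = sum)
  subjects <- sort(unique(agg$subjid))
  horizons <- unique(task_horizon(tasks))
  n_tasks <- length(tasks)
  jd <- list(
    N = nrow(agg), S = length(subjects), T = n_tasks,
    subj = match(agg$subjid, subjects),
    task = match(agg$task, tasks),
    later_mag = agg$later_mag, delay = agg$later_delay,
    sooner_mag = agg$sooner_mag, y = agg$y, n = agg$n)
  if (n_tasks >= 2) {
    jd$Rw <- diag(n_tasks)
    jd$wish_df <- n_tasks + 1
  }
  if (config$reward_scaling) {
    jd$hor <- match(task_horizon(agg$task), horizons)
  }
  model_str <- build_hier_model_string(n_tasks, config$reward_scaling,
                                       length(horizons))
  inits <- lapply(seq_len(config$chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed * 1000L + i,
         mu_logk = rep(-3, n_tasks), mu_logtau = rep(0, n_tasks))
  })
  monitors <- c("mu_logk", "mu_logtau", "sd_b", "sd_u", "b", "u",
                if (n_tasks >= 2) "cor_b" else NULL,
                if (config$reward_scaling) c("mu_logrho", "sd_v", "v") else NULL)
  # JAGS warns if its adaptive samplers would have liked more adaptation
  # iterations; that is informational here -- convergence is gated on
  # R-hat below -- so that one message is muffled.
  jm <- withCallingHandlers(
    rjags::jags.model(textConnection(model_str), data = jd,
                      inits = inits, n.chains = config$chains,
                      n.adapt = config$adapt, quiet = TRUE),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (config$burn > 0) stats::update(jm, config$burn)
  samp <- rjags::coda.samples(jm, monitors, n.iter = config$draws,
                              thin = config$thin)
  samp <- rename_hier_draws(samp, tasks, subjects, horizons)
  pop_pat <- "^(mu_logk|mu_logtau|sd_b|sd_u|mu_logrho|sd_v)"
  pop_cols <- grep(pop_pat, coda::varnames(samp), value = TRUE)
  pop_mcmc <- samp[, pop_cols, drop = FALSE]
  gd <- coda::gelman.diag(pop_mcmc, multivariate = FALSE, autoburnin = FALSE)
  rhat <- gd$psrf[, 1]
  neff <- coda::effectiveSize(pop_mcmc)
  draws <- as.matrix(samp)
  # per subject-task posterior of logk = population level + subject deviation
  subject_logk <- do.call(rbind, lapply(seq_along(tasks), function(t) {
    mu <- draws[, sprintf("mu_logk[%s]", tasks[t])]
    dev <- draws[, sprintf("b[%s,%s]", subjects, tasks[t]), drop = FALSE]
    lk <- dev + mu
    data.frame(subjid = subjects, task = tasks[t],
               logk = colMeans(lk), logk_sd = apply(lk, 2, stats::sd))
  }))
  row.names(subject_logk) <- NULL
  diagnostics <- list(rhat = rhat, max_rhat = max(rhat),
                      n_eff = neff, min_n_eff = min(neff))
  structure(list(
    draws = draws, mcmc = pop_mcmc, subject_logk = subject_logk,
    tasks = tasks, subjects = subjects, horizons = horizons,
    config = config, diagnostics = diagnostics,
    converged = max(rhat) <= config$rhat_limit,
    n_obs = nrow(df)
  ), class = "dd_posterior")
}

rename_hier_draws <- function(samp, tasks, subjects, horizons) {
  vn <- coda::varnames(samp)
  map_idx <- function(nm, labels1, labels2 = NULL) {
    # mu_logk[1] -> mu_logk[NV]; b[2,1] -> b[s02,NV]
    if (is.null(labels2)) {
      idx <- as.integer(sub("^[^\\[]+\\[(\\d+)\\]$", "\\1", nm))
      sprintf("%s[%s]", sub("\\[.*$", "", nm), labels1[idx])
    } else {
      i <- as.integer(sub("^[^\\[]+\\[(\\d+),\\d+\\]$", "\\1", nm))
      j <- as.integer(sub("^[^\\[]+\\[\\d+,(\\d+)\\]$", "\\1", nm))
      sprintf("%s[%s,%s]", sub("\\[.*$", "", nm), labels1[i], labels2[j])
    }
  }
  new <- vn
  for (k in seq_along(vn)) {
    nm <- vn[k]
    base <- sub("\\[.*$", "", nm)
    new[k] <- switch(base,
      mu_logk = , mu_logtau = , sd_b = map_idx(nm, tasks),
      cor_b = map_idx(nm, tasks, tasks),
      b = map_idx(nm, subjects, tasks),
      u = map_idx(nm, subjects),
      mu_logrho = , sd_v = map_idx(nm, horizons),
      v = map_idx(nm, subjects, horizons),
      nm)
  }
  for (ch in seq_along(samp)) {
    colnames(samp[[ch]]) <- new
  }
  samp
}

#' @export
print.dd_posterior <- function(x, ...) {
  cat(sprintf("<dd_posterior> %d tasks (%s), %d subjects, %d draws%s\n",
              length(x$tasks), paste(x$tasks, collapse = ", "),
              length(x$subjects), nrow(x$draws),
              if (x$config$reward_scaling) ", reward-scaling expansion" else ""))
  cat(sprintf("  max R-hat %.3f (%s), min n_eff %.0f\n",
              x$diagnostics$max_rhat,
              if (x$converged) "converged" else "NOT CONVERGED",
              x$diagnostics$min_n_eff))
  invisible(x)
}

assert_converged <- function(fit, force = FALSE) {
  stopifnot(inherits(fit, "dd_posterior"))
  if (!fit$converged && !force) {
    stop(sprintf(
      "hierarchical fit not converged (max R-hat %.3f > %.2f); use force = TRUE to override",
      fit$diagnostics$max_rhat, fit$config$rhat_limit), call. = FALSE)
  }
  invisible(fit)
}

#' Posterior mean and central credible intervals of a parameter
#'
#' @param fit A `dd_posterior`.
#' @param parameter Column name in the draws, e.g. `"mu_logk[NV]"`.
#' @param levels Credible-interval levels (default 80% and 95%).
#' @param force Use an unconverged fit anyway.
#' @return List with `mean`, `sd`, and an `intervals` matrix (one row per
#'   level, columns `lower`, `upper`).
#' @export
posterior_summary <- function(fit, parameter, levels = c(0.8, 0.95),
                              force = FALSE) {
  assert_converged(fit, force)
  if (!parameter %in% colnames(fit$draws)) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  x <- fit$draws[, parameter]
  ints <- t(sapply(levels, function(l) {
    stats::quantile(x, probs = c((1 - l) / 2, 1 - (1 - l) / 2), names = FALSE)
  }))
  dimnames(ints) <- list(paste0(levels * 100, "%"), c("lower", "upper"))
  list(mean = mean(x), sd = stats::sd(x), intervals = ints)
}

#' Evidence ratio for a one-sided hypothesis about the posterior
#'
#' Parses a hypothesis of the form `"a > b"` or `"a < b"`, where each side
#' is a parameter name in the draws or a numeric constant, and returns the
#' posterior probability that it holds together with the evidence ratio
#' `p / (1 - p)` (the posterior odds of the hypothesis against its
#' alternative) and its log2. Probabilities are capped at the draw
#' resolution, with a flag when the cap binds.
#'
#' @param fit A `dd_posterior`.
#' @param hypothesis Character, e.g. `"mu_logk[NV] > mu_logk[LV]"`.
#' @param force Use an unconverged fit anyway.
#' @return A `dd_hypothesis` list: `hypothesis`, `posterior_prob`,
#'   `evidence_ratio`, `log2_evidence_ratio`, `capped`, `one_sided`.
#' @export
evidence_ratio <- function(fit, hypothesis, force = FALSE) {
  assert_converged(fit, force)
  m <- regmatches(hypothesis,
                  regexec("^\\s*(.+?)\\s*([<>])\\s*(.+?)\\s*$", hypothesis))[[1]]
  if (length(m) != 4) {
    stop("hypothesis must have the form 'a > b' or 'a < b'", call. = FALSE)
  }
  side <- function(tok) {
    if (tok %in% colnames(fit$draws)) return(fit$draws[, tok])
    val <- suppressWarnings(as.numeric(tok))
    if (is.na(val)) stop("unknown parameter: ", tok, call. = FALSE)
    val
  }
  lhs <- side(m[2]); rhs <- side(m[4])
  p_raw <- if (m[3] == ">") mean(lhs > rhs) else mean(lhs < rhs)
  ndraw <- nrow(fit$draws)
  cap <- 1 / (2 * ndraw)
  capped <- p_raw < cap || p_raw > 1 - cap
  p <- min(max(p_raw, cap), 1 - cap)
  structure(list(hypothesis = hypothesis, posterior_prob = p_raw,
                 evidence_ratio = p / (1 - p),
                 log2_evidence_ratio = log2(p / (1 - p)),
                 capped = capped, one_sided = TRUE),
            class = "dd_hypothesis")
}

#' @export
print.dd_hypothesis <- function(x, ...) {
  cat(sprintf("<dd_hypothesis> %s : P = %.4f, ER = %.2f (log2 = %.2f)%s\n",
              x$hypothesis, x$posterior_prob, x$evidence_ratio,
              x$log2_evidence_ratio,
              if (x$capped) " [capped at draw resolution]" else ""))
  invisible(x)
}

# Posterior-predictive P(later) for each trial row under each of a subset
# of draws. Returns an n_draws x n_trials matrix.
posterior_choice_prob <- function(fit, trials, draw_idx) {
  df <- as.data.frame(trials)
  s_lab <- df$subjid; t_lab <- df$task
  mu_cols <- match(sprintf("mu_logk[%s]", t_lab), colnames(fit$draws))
  b_cols <- match(sprintf("b[%s,%s]", s_lab, t_lab), colnames(fit$draws))
  tau_mu_cols <- match(sprintf("mu_logtau[%s]", t_lab), colnames(fit$draws))
  u_cols <- match(sprintf("u[%s]", s_lab), colnames(fit$draws))
  if (anyNA(mu_cols) || anyNA(b_cols) || anyNA(tau_mu_cols) || anyNA(u_cols)) {
    stop("trials contain subjects or tasks absent from the fit", call. = FALSE)
  }
  rs <- fit$config$reward_scaling
  if (rs) {
    h_lab <- task_horizon(t_lab)
    rho_mu_cols <- match(sprintf("mu_logrho[%s]", h_lab), colnames(fit$draws))
    v_cols <- match(sprintf("v[%s,%s]", s_lab, h_lab), colnames(fit$draws))
  }
  res <- vapply(draw_idx, function(d) {
    row <- fit$draws[d, ]
    logk <- row[mu_cols] + row[b_cols]
    tau <- exp(row[tau_mu_cols] + row[u_cols])
    rho <- if (rs) exp(row[rho_mu_cols] + row[v_cols]) else 1
    u_l <- (rho * df$later_mag) / (1 + exp(logk) * df$later_delay)
    u_s <- rho * df$sooner_mag
    stats::plogis((u_l - u_s) / tau)
  }, numeric(nrow(df)))
  t(matrix(res, nrow = nrow(df)))
}

#' Bayesian R-squared of a hierarchical fit
#'
#' For each posterior draw, the variance of the predicted choice
#' probabilities over trials divided by that variance plus the expected
#' Bernoulli residual variance `mean(p(1-p))`; summarised over draws.
#'
#' @param fit A `dd_posterior`.
#' @param trials The trial table the fit was (or could have been) fit to.
#' @param per_subject If `TRUE`, return one row per subject.
#' @param n_draws Number of posterior draws to use (default 400).
#' @param force Use an unconverged fit anyway.
#' @return If pooled: list with `mean`, `sd`, `interval` (95%). If
#'   per-subject: data frame `subjid`, `r2`, `r2_sd`.
#' @export
bayes_r2 <- function(fit, trials, per_subject = FALSE, n_draws = 400,
                     force = FALSE) {
  assert_converged(fit, force)
  ndraw <- nrow(fit$draws)
  draw_idx <- round(seq(1, ndraw, length.out = min(n_draws, ndraw)))
  pmat <- posterior_choice_prob(fit, trials, draw_idx)
  r2_of <- function(cols) {
    pv <- pmat[, cols, drop = FALSE]
    ev <- apply(pv, 1, stats::var)
    rv <- rowMeans(pv * (1 - pv))
    ifelse(ev + rv > 0, ev / (ev + rv), 0)
  }
  if (!per_subject) {
    r2 <- r2_of(seq_len(ncol(pmat)))
    return(list(mean = mean(r2), sd = stats::sd(r2),
                interval = stats::quantile(r2, c(0.025, 0.975), names = FALSE)))
  }
  df <- as.data.frame(trials)
  out <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$subjid),
    function(ix) {
      r2 <- r2_of(ix)
      data.frame(r2 = mean(r2), r2_sd = stats::sd(r2))
    }))
  out$subjid <- rownames(out)
  rownames(out) <- NULL
  out[, c("subjid", "r2", "r2_sd")]
}

#' K-fold cross-validation information criterion
#'
#' Splits trials into `k` folds stratified by subject and task (so every
#' training set retains all subjects), refits the hierarchical model on
#' each training set, accumulates the held-out pointwise log posterior
#' predictive density, and returns `-2 * elpd` (lower is better).
#'
#' @param trials A trial table.
#' @param config A [hier_config()].
#' @param k Number of folds (>= 2; default 10).
#' @param seed Integer seed for the fold assignment.
#' @param n_draws Posterior draws used for the held-out density (default 500).
#' @return A `dd_kfold` list: `kfold_ic`, `elpd`, `pointwise` (per-trial
#'   elpd contributions in `trials` row order), `k`, `n`, `folds`.
#' @export
kfold_ic <- function(trials, config = hier_config(), k = 10, seed = 1,
                     n_draws = 500) {
  stopifnot(k >= 2)
  df <- as.data.frame(trials)
  n <- nrow(df)
  folds <- integer(n)
  with_seed(seed, {
    for (ix in split(seq_len(n), paste(df$subjid, df$task))) {
      folds[ix] <- (sample(rev(seq_along(ix))) %% k) + 1L
    }
  })
  pointwise <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    train <- trials[folds != f, , drop = FALSE]
    test <- trials[folds == f, , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- fit_hierarchical(train, cfg)
    if (!fit$converged) {
      warning(sprintf("fold %d fit exceeded the R-hat limit (%.3f)",
                      f, fit$diagnostics$max_rhat))
    }
    ndraw <- nrow(fit$draws)
    draw_idx <- round(seq(1, ndraw, length.out = min(n_draws, ndraw)))
    pmat <- posterior_choice_prob(fit, test, draw_idx)
    lik <- pmat
    not_later <- !test$chose_later
    lik[, not_later] <- 1 - lik[, not_later, drop = FALSE]
    # pointwise elpd: log of the draw-averaged likelihood of each trial
    pointwise[folds == f] <- log(pmax(colMeans(lik), DD_PROB_EPS))
  }
  elpd <- sum(pointwise)
  structure(list(kfold_ic = -2 * elpd, elpd = elpd, pointwise = pointwise,
                 k = k, n = n, folds = folds),
            class = "dd_kfold")
}

#' Compare two K-fold results on identical data
#'
#' The difference in KfoldIC with a standard error computed from the
#' per-trial pointwise contributions (valid only when both results used
#' the same trials and fold assignment seed).
#'
#' @param a,b `dd_kfold` objects from [kfold_ic()] on the same trials.
#' @return List with `delta_kfold_ic` (`a` minus `b`; negative favours
#'   `a`), `se`, `delta_elpd`, `better`.
#' @export
kfold_compare <- function(a, b) {
  stopifnot(inherits(a, "dd_kfold"), inherits(b, "dd_kfold"))
  if (a$n != b$n) stop("k-fold results are not on identical data", call. = FALSE)
  d <- a$pointwise - b$pointwise
  delta_elpd <- sum(d)
  se_elpd <- sqrt(length(d) * stats::var(d))
  list(delta_kfold_ic = -2 * delta_elpd, se = 2 * se_elpd,
       delta_elpd = delta_elpd,
       better = if (delta_elpd > 0) "a" else "b")
}

#' Fit the reward-scaling expansion of the hierarchical model
#'
#' Same as [fit_hierarchical()] with the per-horizon reward-scaling
#' parameter enabled (log-link, prior centred at rho = 1).
#'
#' @param trials A trial table.
#' @param config A [hier_config()]; its `reward_scaling` flag is set.
#' @return A `dd_posterior`.
#' @export
fit_reward_scaling_model <- function(trials, config = hier_config()) {
  config$reward_scaling <- TRUE
  fit_hierarchical(trials, config)
}
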
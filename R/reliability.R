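#' Correlation with a 95% confidence interval
#'
#' Pearson correlations get a Fisher-z interval; Spearman rank correlations
#' get a percentile bootstrap interval (no standard closed form).
#'
#' @param x,y Equal-length numeric vectors, n >= 4.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_boot Bootstrap resamples for the Spearman interval
#'   (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return List with `r`, `ci` (length 2), `method`, `n`.
#' @export
correlation_with_ci <- function(x, y, method = c("pearson", "spearman"),
                                n_boot = 10000, conf = 0.95, seed = 1) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  if (method == "pearson") {
    ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf)
    return(list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
                method = method, n = n))
  }
  r <- stats::cor(x, y, method = "spearman")
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ix <- sample.int(n, replace = TRUE)
      suppressWarnings(stats::cor(x[ix], y[ix], method = "spearman"))
    }, numeric(1))
  })
  ci <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, na.rm = TRUE)
  list(r = r, ci = ci, method = method, n = n)
}

#' Simulation ceiling for an observed cross-task rank correlation
#'
#' Estimation noise attenuates between-task correlations even when the
#' true subject ranks agree perfectly. This simulates pairs of tasks whose
#' generating log(k) values share a single subject factor (perfect rank
#' agreement), runs the same per-subject estimator used for the observed
#' data on both, and returns the mean attainable Spearman correlation over
#' replicates -- the ceiling against which observed correlations are
#' normalised.
#'
#' @param schedule_a,schedule_b [schedule_config()]s of the two tasks.
#' @param n_subjects Number of simulated subjects per replicate.
#' @param mean_logk,sd_logk Length-2 vectors (task a, task b) of the
#'   generating log(k) population mean and SD.
#' @param tau Length-2 vector of decision noise for the two tasks.
#' @param n_rep Number of replicates (default 500).
#' @param spec Generating and fitting [model_spec()].
#' @param seed Integer seed.
#' @return List with `ceiling` (mean Spearman r), `reps` (per-replicate
#'   values), and the simulation settings.
#' @export
attenuation_ceiling <- function(schedule_a, schedule_b,
                                n_subjects = 63,
                                mean_logk = c(-3.49, -3.2),
                                sd_logk = c(0.8, 1.1),
                                tau = c(0.8, 1.5),
                                n_rep = 500,
                                spec = model_spec(),
                                seed = 1) {
  stopifnot(inherits(schedule_a, "dd_schedule_config"),
            inherits(schedule_b, "dd_schedule_config"))
  reps <- with_seed(seed, {
    vapply(seq_len(n_rep), function(rep) {
      z <- stats::rnorm(n_subjects)
      est <- matrix(NA_real_, n_subjects, 2)
      for (j in 1:2) {
        sched_cfg <- if (j == 1) schedule_a else schedule_b
        for (s in seq_len(n_subjects)) {
          agent <- list(subjid = sprintf("s%03d", s),
                        logk = mean_logk[j] + sd_logk[j] * z[s],
                        tau = tau[j], alpha = 1, rho = 1)
          sched <- make_offer_schedule(sched_cfg, seed = NULL)
          tr <- simulate_choices(agent, sched, task = sched_cfg$task,
                                 spec = spec, seed = NULL)
          f <- fit_subject_mle(tr, spec = spec, n_starts = 3)
          if (isTRUE(f$converged)) est[s, j] <- f$logk
        }
      }
      ok <- stats::complete.cases(est)
      stats::cor(est[ok, 1], est[ok, 2], method = "spearman")
    }, numeric(1))
  })
  list(ceiling = mean(reps), reps = reps, n_rep = n_rep,
       n_subjects = n_subjects, seed = seed)
}

#' Attenuation-corrected rank correlation
#'
#' Divides an observed rank correlation by the simulation ceiling (the
#' expected maximum attainable correlation given estimation noise,
#' see [attenuation_ceiling()]). Corrected values are capped at 1 with a
#' flag when the observed exceeds the ceiling.
#'
#' @param observed_r Observed Spearman correlation.
#' @param ceiling The simulation ceiling, or the list returned by
#'   [attenuation_ceiling()].
#' @param observed_ci Optional observed-correlation interval to rescale.
#' @return List with `corrected_r`, `ceiling`, `capped`, and
#'   `corrected_ci` when an interval was supplied.
#' @export
corrected_rank_correlation <- function(observed_r, ceiling,
                                       observed_ci = NULL) {
  if (is.list(ceiling)) ceiling <- ceiling$ceiling
  if (!is.finite(ceiling) || ceiling <= 0) {
    stop("ceiling must be positive", call. = FALSE)
  }
  corrected <- observed_r / ceiling
  capped <- corrected > 1
  out <- list(corrected_r = min(corrected, 1), ceiling = ceiling,
              capped = capped)
  if (!is.null(observed_ci)) {
    out$corrected_ci <- pmin(observed_ci / ceiling, 1)
  }
  out
}

#' Compare two dependent overlapping correlations
#'
#' Tests whether `cor(x1, x2)` differs from `cor(x1, x3)` measured on the
#' same `n` subjects (dependent correlations sharing variable 1), using
#' Steiger's (1980) modified Fisher-z statistic and Williams' (1959) t.
#'
#' @param r12,r13 The two correlations being compared (sharing variable 1).
#' @param r23 The correlation between the non-shared variables.
#' @param n Sample size.
#' @return Data frame with one row per method: `statistic`, `df`
#'   (NA for the z test), `p` (two-sided).
#' @export
compare_dependent_correlations <- function(r12, r13, r23, n) {
  stopifnot(n > 4)
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    stop("degenerate case: |r| must be < 1", call. = FALSE)
  }
  rbar <- (r12 + r13) / 2
  # Steiger's z using the average-correlation covariance approximation
  cov_term <- (r23 * (1 - 2 * rbar^2) -
                 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)) / (1 - rbar^2)^2
  z12 <- atanh(r12); z13 <- atanh(r13)
  z_stat <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * cov_term))
  p_z <- 2 * stats::pnorm(-abs(z_stat))
  # Williams' t with df = n - 3
  K <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  t_stat <- (r12 - r13) *
    sqrt((n - 1) * (1 + r23) /
           (2 * K * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3))
  p_t <- 2 * stats::pt(-abs(t_stat), df = n - 3)
  data.frame(method = c("steiger", "williams"),
             statistic = c(z_stat, t_stat),
             df = c(NA_real_, n - 3),
             p = c(p_z, p_t))
}

#' Bootstrap / permutation test of a sample statistic
#'
#' Unpaired one-sample: bootstraps the statistic of `x` and locates 0 in
#' the bootstrap distribution (two-sided). Unpaired two-sample: bootstraps
#' the difference in the statistic between the groups and locates 0.
#' Paired: a sign-flip permutation test of the mean paired difference.
#' Deterministic given the seed.
#'
#' @param x Numeric sample.
#' @param y Optional second sample (required when `paired = TRUE`).
#' @param statistic `"mean"`, `"median"` or `"variance"`.
#' @param n_boot Number of resamples (default 10000).
#' @param paired Paired test (permutation of signs of `x - y`).
#' @param seed Integer seed.
#' @return List with `p`, `boot` (the resampled statistics), `observed`,
#'   `degenerate` flag (constant data: `p` reported at the boundary).
#' @export
bootstrap_test <- function(x, y = NULL,
                           statistic = c("mean", "median", "variance"),
                           n_boot = 10000, paired = FALSE, seed = 1) {
  statistic <- match.arg(statistic)
  stat_fn <- switch(statistic, mean = mean, median = stats::median,
                    variance = stats::var)
  if (paired) {
    if (is.null(y) || length(y) != length(x)) {
      stop("paired test needs equal-length x and y", call. = FALSE)
    }
    d <- x - y
    if (all(d == d[1])) {
      return(list(p = 1, boot = rep(mean(d), n_boot), observed = mean(d),
                  degenerate = TRUE))
    }
    obs <- mean(d)
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        mean(d * sample(c(-1, 1), length(d), replace = TRUE))
      }, numeric(1))
    })
    p <- (sum(abs(boot) >= abs(obs)) + 1) / (n_boot + 1)
    return(list(p = p, boot = boot, observed = obs, degenerate = FALSE))
  }
  if (length(x) < 2 || (!is.null(y) && length(y) < 2)) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  boot <- with_seed(seed, {
    if (is.null(y)) {
      vapply(seq_len(n_boot), function(b) {
        stat_fn(sample(x, replace = TRUE))
      }, numeric(1))
    } else {
      vapply(seq_len(n_boot), function(b) {
        stat_fn(sample(x, replace = TRUE)) - stat_fn(sample(y, replace = TRUE))
      }, numeric(1))
    }
  })
  obs <- if (is.null(y)) stat_fn(x) else stat_fn(x) - stat_fn(y)
  degenerate <- stats::sd(boot) == 0
  if (degenerate) {
    p <- if (all(boot == 0)) 1 else 1 / (n_boot + 1)
    return(list(p = p, boot = boot, observed = obs, degenerate = TRUE))
  }
  lower <- mean(boot <= 0); upper <- mean(boot >= 0)
  p <- min(1, 2 * min(lower, upper))
  list(p = p, boot = boot, observed = obs, degenerate = FALSE)
}

#' Cross-task regression of discount factors
#'
#' Ordinary least squares of one task's log(k) on the other tasks', with
#' the overall F test and R-squared, plus likelihood-ratio tests for each
#' optional extra factor (e.g. early-block mean reward, early fraction
#' later) obtained by dropping it from the full model.
#'
#' @param logk_table Wide data frame: `subjid` plus one numeric column per
#'   task, plus any extra-factor columns.
#' @param response_task Column name of the response.
#' @param predictor_tasks Column names of the task predictors.
#' @param extra_factors Optional column names of nuisance factors to test.
#' @return A `dd_regression` list: `coefficients` (estimate, SE, p),
#'   `f` (statistic, df, p), `r_squared`, `lr_tests` (one row per extra
#'   factor), `model`.
#' @export
cross_task_regression <- function(logk_table, response_task,
                                  predictor_tasks, extra_factors = NULL) {
  cols <- c(response_task, predictor_tasks, extra_factors)
  missing <- setdiff(cols, names(logk_table))
  if (length(missing) > 0) {
    stop("logk_table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dat <- logk_table[stats::complete.cases(logk_table[, cols]), cols,
                    drop = FALSE]
  rhs <- c(predictor_tasks, extra_factors)
  fml <- stats::reformulate(sprintf("`%s`", rhs),
                            response = sprintf("`%s`", response_task))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  coefs <- data.frame(term = gsub("`", "", rownames(sm$coefficients)),
                      estimate = sm$coefficients[, 1],
                      se = sm$coefficients[, 2],
                      p = sm$coefficients[, 4],
                      row.names = NULL)
  fstat <- sm$fstatistic
  lr_tests <- NULL
  if (!is.null(extra_factors)) {
    lr_tests <- do.call(rbind, lapply(extra_factors, function(fac) {
      reduced_rhs <- setdiff(rhs, fac)
      fml_r <- stats::reformulate(sprintf("`%s`", reduced_rhs),
                                  response = sprintf("`%s`", response_task))
      fit_r <- stats::lm(fml_r, data = dat)
      lr <- 2 * (as.numeric(stats::logLik(fit)) -
                   as.numeric(stats::logLik(fit_r)))
      data.frame(factor = fac, lr_chisq = lr, df = 1,
                 p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
    }))
  }
  structure(list(
    coefficients = coefs,
    f = list(statistic = unname(fstat[1]), df1 = unname(fstat[2]),
             df2 = unname(fstat[3]),
             p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    r_squared = sm$r.squared,
    lr_tests = lr_tests,
    model = fit
  ), class = "dd_regression")
}

#' Variance decomposition of log(k) over the horizon and modality gaps
#'
#' Linear mixed model of per-subject, per-task log(k) on two gap
#' indicators -- `days` (TRUE only for the long task, whose offers are in
#' days) and `verbal` (TRUE for both verbal tasks) -- with a subject random
#' intercept, fit by maximum likelihood so that likelihood-ratio tests of
#' the fixed effects are valid. Each factor is tested by dropping it and
#' comparing AIC and the LR chi-square, reproducing a two-factor vs.
#' one-factor model comparison.
#'
#' @param logk_long Data frame with columns `subjid`, `task`, `logk`,
#'   `days` (logical), `verbal` (logical).
#' @return A `dd_regression`-style list: `coefficients` (estimate, SE, p
#'   from the t statistic with residual-based normal approximation),
#'   `aic_table` (full model and each reduced model with LR p), `model`.
#' @export
gap_variance_mixed_model <- function(logk_long) {
  req <- c("subjid", "task", "logk", "days", "verbal")
  missing <- setdiff(req, names(logk_long))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tasks_per_subj <- tapply(logk_long$task, logk_long$subjid,
                           function(t) length(unique(t)))
  if (any(tasks_per_subj < 2)) {
    stop("every subject needs at least 2 tasks", call. = FALSE)
  }
  dat <- logk_long
  dat$days <- as.logical(dat$days)
  dat$verbal <- as.logical(dat$verbal)
  full <- lme4::lmer(logk ~ days + verbal + (1 | subjid), data = dat,
                     REML = FALSE)
  red_days <- lme4::lmer(logk ~ verbal + (1 | subjid), data = dat,
                         REML = FALSE)
  red_verbal <- lme4::lmer(logk ~ days + (1 | subjid), data = dat,
                           REML = FALSE)
  lr <- function(reduced) {
    stat <- 2 * (as.numeric(stats::logLik(full)) -
                   as.numeric(stats::logLik(reduced)))
    list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  lr_d <- lr(red_days); lr_v <- lr(red_verbal)
  sm <- summary(full)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      p = 2 * stats::pnorm(-abs(sm[, 3])), row.names = NULL)
  aic_table <- data.frame(
    dropped = c("none", "verbal", "days"),
    delta_df = c(NA, 1, 1),
    aic = c(stats::AIC(full), stats::AIC(red_verbal), stats::AIC(red_days)),
    lr_p = c(NA, lr_v$p, lr_d$p))
  structure(list(coefficients = coefs, aic_table = aic_table, model = full),
            class = "dd_regression")
}

#' Test-retest stability of model-free time preferences
#'
#' Splits each subject's trials either between the first and second half
#' of each reward block (`half_block`) or between the first two sessions
#' of each task (`session`), computes the fraction of later choices per
#' split half, and reports the paired Pearson correlation and a Wilcoxon
#' signed-rank test of the difference. Subjects with an empty cell are
#' dropped with a warning; constant (deterministic) subjects make the
#' correlation undefined and are flagged.
#'
#' @param trials A trial table.
#' @param split `"half_block"` or `"session"`.
#' @return List with `per_subject` (subjid, task, f1, f2), `pearson_r`,
#'   `wilcoxon_p`, `n`, `degenerate` flag.
#' @export
test_retest_summary <- function(trials, split = c("half_block", "session")) {
  split <- match.arg(split)
  df <- as.data.frame(trials)
  cells <- split(df, list(df$subjid, df$task), drop = TRUE)
  rows <- lapply(cells, function(cell) {
    if (split == "half_block") {
      cell$half <- NA_integer_
      for (ix in split(seq_len(nrow(cell)), cell$block)) {
        ord <- ix[order(cell$trial[ix])]
        first <- ord[seq_len(ceiling(length(ord) / 2))]
        cell$half[first] <- 1L
        cell$half[setdiff(ord, first)] <- 2L
      }
    } else {
      sess <- sort(unique(cell$session))
      if (length(sess) < 2) return(NULL)
      cell <- cell[cell$session %in% sess[1:2], , drop = FALSE]
      cell$half <- ifelse(cell$session == sess[1], 1L, 2L)
    }
    f1 <- mean(cell$chose_later[cell$half == 1])
    f2 <- mean(cell$chose_later[cell$half == 2])
    if (is.nan(f1) || is.nan(f2)) return(NULL)
    data.frame(subjid = cell$subjid[1], task = cell$task[1], f1 = f1, f2 = f2)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warning(sprintf("%d subject-task cell(s) dropped (empty split cell)",
                    dropped))
  }
  per_subject <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_subject) || nrow(per_subject) < 3) {
    stop("not enough subject-task cells with both split halves", call. = FALSE)
  }
  row.names(per_subject) <- NULL
  degenerate <- stats::sd(per_subject$f1) == 0 || stats::sd(per_subject$f2) == 0
  r <- if (degenerate) NA_real_ else stats::cor(per_subject$f1, per_subject$f2)
  w <- suppressWarnings(
    stats::wilcox.test(per_subject$f1, per_subject$f2, paired = TRUE))
  list(per_subject = per_subject, pearson_r = r, wilcoxon_p = w$p.value,
       n = nrow(per_subject), degenerate = degenerate)
}
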
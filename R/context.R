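#' Per-trial utility differences under fitted subject parameters
#'
#' Converts each offer into a difference in subjective utility,
#' `delta_u = U_later - U_sooner`, using each subject's task-specific
#' fitted log(k) (hyperbolic utility), and tags the first `early_max`
#' trials of each subject-task as early. This pools offers across subjects
#' onto a common utility axis for the adaptation analysis.
#'
#' @param trials A trial table.
#' @param fits Data frame with columns `subjid`, `task`, `logk` -- e.g. the
#'   `subject_logk` element of a [fit_hierarchical()] result, or a
#'   [fit_cohort_mle()] table.
#' @param early_max Trials at the start of a task counted as early
#'   (default 4).
#' @return Data frame of adaptation records: `subjid`, `task`, `trial`,
#'   `early`, `delta_u`, `chose_later`. Subjects without a fit are skipped
#'   with a warning.
#' @export
delta_utility <- function(trials, fits, early_max = 4) {
  df <- as.data.frame(trials)
  key <- paste(df$subjid, df$task)
  fit_key <- paste(fits$subjid, fits$task)
  idx <- match(key, fit_key)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    warning(sprintf("no fitted parameters for %d subject-task cell(s); skipped",
                    length(miss)))
  }
  keep <- !is.na(idx)
  df <- df[keep, , drop = FALSE]
  idx <- idx[keep]
  k <- exp(fits$logk[idx])
  u_l <- df$later_mag / (1 + k * df$later_delay)
  out <- data.frame(
    subjid = df$subjid, task = df$task, trial = df$trial,
    early = df$trial <= early_max,
    delta_u = u_l - df$sooner_mag,
    chose_later = df$chose_later)
  out[order(out$subjid, out$task, out$trial), , drop = FALSE]
}

#' Early-trial adaptation mixed logistic model
#'
#' Fits a mixed-effects logistic regression of choice on the utility
#' difference with a short-task indicator, an early-trial indicator and
#' their interaction, plus a per-subject random intercept and utility
#' slope (Laplace-approximate maximum likelihood):
#'
#' full:    `choice ~ delta_u + sv:delta_u + sv * early + (1 + delta_u | subjid)`
#'
#' reduced: `choice ~ delta_u + sv:delta_u + sv + (1 + delta_u | subjid)`
#'
#' The adaptation effect is tested by the likelihood-ratio chi-square
#' (2 df: the early main effect and the task-by-early interaction).
#'
#' @param records Adaptation records from [delta_utility()], restricted to
#'   two tasks; the task named in `short_task` is coded as the `sv`
#'   indicator.
#' @param short_task Task treated as the short-horizon level (default `SV`).
#' @param nAGQ Integrand approximation passed to [lme4::glmer()] (1 =
#'   Laplace; 0 is faster and slightly cruder).
#' @return A `dd_adaptation` list: `coefficients` (estimate, SE, z, p),
#'   `lr` (chisq, df, p), `aic` (full, reduced), `flagged` (convergence or
#'   separation messages), `models`.
#' @export
adaptation_glmm <- function(records, short_task = "SV", nAGQ = 1) {
  tasks <- unique(records$task)
  if (length(tasks) != 2 || !short_task %in% tasks) {
    stop("records must cover exactly 2 tasks including the short task",
         call. = FALSE)
  }
  dat <- records
  dat$sv <- dat$task == short_task
  if (!any(dat$early) || !all(tapply(dat$early, dat$sv, any))) {
    stop("both tasks need early and late trials", call. = FALSE)
  }
  msgs <- character()
  fit_one <- function(fml) {
    withCallingHandlers(
      lme4::glmer(fml, data = dat, family = stats::binomial(), nAGQ = nAGQ,
                  control = lme4::glmerControl(optimizer = "bobyqa",
                                               calc.derivs = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
  }
  full <- fit_one(chose_later ~ delta_u + sv:delta_u + sv * early +
                    (1 + delta_u | subjid))
  reduced <- fit_one(chose_later ~ delta_u + sv:delta_u + sv +
                       (1 + delta_u | subjid))
  lr_stat <- 2 * (as.numeric(stats::logLik(full)) -
                    as.numeric(stats::logLik(reduced)))
  sm <- summary(full)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL)
  # fitted probabilities pinned at 0/1 indicate (quasi-)separation
  p_hat <- stats::fitted(full)
  if (any(p_hat < 1e-10 | p_hat > 1 - 1e-10)) {
    msgs <- c(msgs, "possible separation: fitted probabilities at 0/1")
  }
  structure(list(
    coefficients = coefs,
    lr = list(chisq = lr_stat, df = 2,
              p = stats::pchisq(lr_stat, df = 2, lower.tail = FALSE)),
    aic = c(full = stats::AIC(full), reduced = stats::AIC(reduced)),
    flagged = unique(msgs),
    models = list(full = full, reduced = reduced)
  ), class = "dd_adaptation")
}

#' @export
print.dd_adaptation <- function(x, ...) {
  cat(sprintf("<dd_adaptation> LR chisq(%d) = %.2f, p = %.2g; AIC full %.1f vs reduced %.1f\n",
              x$lr$df, x$lr$chisq, x$lr$p, x$aic["full"], x$aic["reduced"]))
  if (length(x$flagged)) cat("  flags:", length(x$flagged), "message(s)\n")
  invisible(x)
}

#' Shift and scale comparisons of log(k) between tasks
#'
#' For every pair of fitted tasks, computes one-sided evidence ratios
#' (reported as log2) that the population mean log(k) of one task exceeds
#' the other's, and that the across-subject SD of log(k) (the subject-
#' deviation SD) of one exceeds the other's. Means are compared in each
#' task's native units unless `convert_to` is given, in which case
#' population-mean draws are shifted by the log unit ratio before
#' comparison; scale (SD) comparisons are invariant to units.
#'
#' @param fit A `dd_posterior` from [fit_hierarchical()].
#' @param convert_to Optional common unit (`"second"`, `"day"`, `"week"`)
#'   for the mean comparisons.
#' @param force Use an unconverged fit anyway.
#' @return Data frame with columns `comparison`, `type` (`mean`/`sd`),
#'   `posterior_prob`, `log2_evidence_ratio`, `units`.
#' @export
shift_scale_report <- function(fit, convert_to = NULL, force = FALSE) {
  assert_converged(fit, force)
  tasks <- fit$tasks
  if (length(tasks) < 2) stop("need at least 2 tasks", call. = FALSE)
  shift_for <- function(task) {
    if (is.null(convert_to)) return(0)
    # re-expressing k per convert_to-unit multiplies it by the unit ratio
    log(unit_seconds(convert_to) / unit_seconds(task_delay_unit(task)))
  }
  rows <- list()
  for (i in seq_along(tasks)) for (j in seq_along(tasks)) {
    if (i >= j) next
    a <- tasks[i]; b <- tasks[j]
    mu_a <- fit$draws[, sprintf("mu_logk[%s]", a)] + shift_for(a)
    mu_b <- fit$draws[, sprintf("mu_logk[%s]", b)] + shift_for(b)
    sd_a <- fit$draws[, sprintf("sd_b[%s]", a)]
    sd_b_ <- fit$draws[, sprintf("sd_b[%s]", b)]
    ndraw <- nrow(fit$draws)
    cap <- 1 / (2 * ndraw)
    pm <- min(max(mean(mu_a > mu_b), cap), 1 - cap)
    ps <- min(max(mean(sd_a > sd_b_), cap), 1 - cap)
    units <- if (is.null(convert_to)) {
      sprintf("native (%s vs %s)", task_delay_unit(a), task_delay_unit(b))
    } else convert_to
    rows[[length(rows) + 1]] <- data.frame(
      comparison = sprintf("%s > %s", a, b),
      type = c("mean", "sd"),
      posterior_prob = c(pm, ps),
      log2_evidence_ratio = log2(c(pm / (1 - pm), ps / (1 - ps))),
      units = c(units, "unit-invariant"))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
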
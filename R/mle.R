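#' Maximum-likelihood fit of one subject's choices in one task
#'
#' Minimises the negative log-likelihood over link-scale parameters
#' (log(k) unconstrained; tau, alpha, rho through log-links) from a
#' multi-start grid spanning log(k) in [-12, 2] and log(tau) in [-3, 3],
#' keeping the best of `n_starts` starts. Standard errors come from the
#' inverse of the observed information (numerical Hessian at the optimum).
#' Subjects whose choices are all the same (always later or always sooner)
#' are flagged as insensitive and not fit.
#'
#' @param trials Trial table for a single subject and task.
#' @param spec A [model_spec()].
#' @param n_starts Number of optimiser starts (>= 5 recommended).
#' @param seed Integer seed for the (deterministic given seed) start grid.
#' @return A `dd_subject_fit` list with elements `subjid`, `task`, `logk`,
#'   `logk_se`, `tau`, `tau_se`, optional `alpha`/`rho` (+ SEs), `nll`,
#'   `converged`, `insensitive`, `pseudo_r2`, `n_trials`, `par` (link-scale
#'   optimum), `spec`.
#' @export
fit_subject_mle <- function(trials, spec = model_spec(), n_starts = 5,
                            seed = 1) {
  subjid <- unique(as.character(trials$subjid))
  task <- unique(as.character(trials$task))
  if (length(subjid) != 1 || length(task) != 1) {
    stop("fit_subject_mle expects trials from a single subject and task",
         call. = FALSE)
  }
  n <- nrow(trials)
  base <- list(subjid = subjid, task = task, n_trials = n, spec = spec,
               logk = NA_real_, logk_se = NA_real_,
               tau = NA_real_, tau_se = NA_real_,
               nll = NA_real_, pseudo_r2 = NA_real_,
               converged = FALSE, insensitive = FALSE, par = NULL)
  class(base) <- "dd_subject_fit"
  frac <- mean(trials$chose_later)
  if (n < 2 || frac %in% c(0, 1)) {
    base$insensitive <- TRUE
    return(base)
  }
  # plain numeric vectors: the NLL is evaluated thousands of times
  lm_ <- trials$later_mag; ld_ <- trials$later_delay
  sm_ <- trials$sooner_mag; y_ <- trials$chose_later
  npar <- length(model_par_names(spec))
  nll_fn <- function(theta) {
    p <- choice_prob_later(
      lm_, ld_, sm_, 0,
      logk = theta[1], tau = exp(theta[2]),
      alpha = if (spec$curvature) exp(theta[3]) else 1,
      rho = if (spec$reward_scaling) exp(theta[npar]) else 1,
      spec = spec)
    p <- clip_prob(p)
    -sum(ifelse(y_, log(p), log1p(-p)))
  }
  starts <- mle_start_grid(npar, n_starts, seed)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], nll_fn, method = "Nelder-Mead",
                   control = list(maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) return(base)
  # polish with a gradient step from the best simplex solution
  polished <- tryCatch(
    stats::optim(best$par, nll_fn, method = "BFGS",
                 control = list(maxit = 200)),
    error = function(e) best)
  if (polished$value <= best$value) best <- polished
  hess <- tryCatch(stats::optimHess(best$par, nll_fn), error = function(e) NULL)
  se <- rep(NA_real_, npar)
  if (!is.null(hess)) {
    inv <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(inv)) {
      d <- diag(inv)
      se <- ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  theta <- best$par
  base$logk <- theta[1]
  base$logk_se <- se[1]
  base$tau <- exp(theta[2])
  base$tau_se <- exp(theta[2]) * se[2]   # delta method through the log-link
  if (spec$curvature) {
    base$alpha <- exp(theta[3]); base$alpha_se <- exp(theta[3]) * se[3]
  }
  if (spec$reward_scaling) {
    base$rho <- exp(theta[npar]); base$rho_se <- exp(theta[npar]) * se[npar]
  }
  base$nll <- best$value
  base$par <- theta
  base$converged <- is.finite(best$value)
  # McFadden pseudo-R2 against the constant-probability null model
  nll0 <- -n * (frac * log(frac) + (1 - frac) * log(1 - frac))
  base$pseudo_r2 <- 1 - best$value / nll0
  base
}

mle_start_grid <- function(npar, n_starts, seed) {
  with_seed(seed, {
    logk0 <- seq(-10, 0, length.out = max(n_starts, 2))
    grid <- cbind(logk0, rep(0, length(logk0)))
    if (npar > 2) {
      grid <- cbind(grid, matrix(0, nrow(grid), npar - 2))
    }
    # jitter all but the first start so repeated starts are not collinear
    jitter <- matrix(stats::rnorm(length(grid), 0, 0.5), nrow(grid))
    jitter[1, ] <- 0
    grid + jitter
  })
}

#' Fit every subject-task cell of a dataset by maximum likelihood
#'
#' @param trials A trial table covering one or more subjects and tasks.
#' @param spec A [model_spec()].
#' @param ... Passed to [fit_subject_mle()].
#' @return Data frame with one row per subject-task: estimates, standard
#'   errors, `nll`, `pseudo_r2`, `converged`, `insensitive`, `n_trials`.
#' @export
fit_cohort_mle <- function(trials, spec = model_spec(), ...) {
  cells <- unique(as.data.frame(trials)[, c("subjid", "task")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$subjid == cells$subjid[i] &
                    trials$task == cells$task[i], , drop = FALSE]
    f <- fit_subject_mle(sub, spec = spec, ...)
    data.frame(
      subjid = f$subjid, task = f$task,
      logk = f$logk, logk_se = f$logk_se,
      tau = f$tau, tau_se = f$tau_se,
      alpha = f$alpha %||% NA_real_,
      rho = f$rho %||% NA_real_,
      nll = f$nll, pseudo_r2 = f$pseudo_r2,
      converged = f$converged, insensitive = f$insensitive,
      n_trials = f$n_trials
    )
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Bayesian information criterion of a subject fit
#'
#' `BIC = p * log(n) + 2 * NLL` with `p` free parameters and `n` trials.
#'
#' @param fit A `dd_subject_fit` from [fit_subject_mle()].
#' @return BIC value. Errors if the fit did not converge.
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "dd_subject_fit"))
  if (!isTRUE(fit$converged)) {
    stop("BIC requires a converged fit", call. = FALSE)
  }
  p <- length(model_par_names(fit$spec))
  p * log(fit$n_trials) + 2 * fit$nll
}

#' Leave-one-trial-out cross-validated log-likelihood
#'
#' For each trial, refits the model on the remaining trials (warm-started
#' at the full-data optimum) and evaluates the held-out trial's
#' log-likelihood; returns the mean. Folds whose refit fails are reported
#' in the result, not silently dropped.
#'
#' @param trials Trial table for a single subject and task.
#' @param spec A [model_spec()].
#' @param ... Passed to the initial [fit_subject_mle()].
#' @return List with `mean_loglik`, per-trial `loglik`, and `failed_folds`
#'   (indices whose refit did not converge).
#' @export
loo_cv_score <- function(trials, spec = model_spec(), ...) {
  full <- fit_subject_mle(trials, spec = spec, ...)
  if (!isTRUE(full$converged)) {
    stop("full-data fit failed; cannot cross-validate", call. = FALSE)
  }
  n <- nrow(trials)
  ll <- rep(NA_real_, n)
  failed <- integer()
  for (i in seq_len(n)) {
    train <- trials[-i, , drop = FALSE]
    lm_ <- train$later_mag; ld_ <- train$later_delay
    sm_ <- train$sooner_mag; y_ <- train$chose_later
    npar <- length(full$par)
    nll_fn <- function(theta) {
      p <- clip_prob(choice_prob_later(
        lm_, ld_, sm_, 0, logk = theta[1], tau = exp(theta[2]),
        alpha = if (spec$curvature) exp(theta[3]) else 1,
        rho = if (spec$reward_scaling) exp(theta[npar]) else 1,
        spec = spec))
      -sum(ifelse(y_, log(p), log1p(-p)))
    }
    refit <- tryCatch(
      stats::optim(full$par, nll_fn, method = "Nelder-Mead",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(refit) || !is.finite(refit$value)) {
      failed <- c(failed, i)
      next
    }
    params <- list(logk = refit$par[1], tau = exp(refit$par[2]))
    if (spec$curvature) params$alpha <- exp(refit$par[3])
    if (spec$reward_scaling) params$rho <- exp(refit$par[npar])
    ll[i] <- trial_loglik(trials[i, , drop = FALSE], params, spec)
  }
  list(mean_loglik = mean(ll, na.rm = TRUE), loglik = ll,
       failed_folds = failed)
}

#' Compare discounting model classes across a cohort
#'
#' Fits every class to every subject-task cell on identical data, reports
#' per-class mean BIC with its standard error across cells and the number
#' of cells "well described" (McFadden pseudo-R2 >= `well_described_r2`),
#' and selects the class with the lowest mean BIC, breaking ties toward
#' fewer parameters.
#'
#' @param trials A trial table.
#' @param classes Named list of [model_spec()]s
#'   (default [standard_model_classes()]).
#' @param well_described_r2 Pseudo-R2 threshold (default 0.2).
#' @param ... Passed to [fit_subject_mle()].
#' @return A `dd_model_comparison` list: `table` (per-class mean BIC, SE,
#'   mean pseudo-R2, number well described, failures), `selected`, `fits`
#'   (per-class cohort fit tables).
#' @export
compare_model_classes <- function(trials, classes = standard_model_classes(),
                                  well_described_r2 = 0.2, ...) {
  stopifnot(length(classes) >= 2, !is.null(names(classes)))
  fits <- lapply(classes, function(sp) fit_cohort_mle(trials, spec = sp, ...))
  n_cells <- nrow(fits[[1]])
  rows <- lapply(names(classes), function(nm) {
    f <- fits[[nm]]
    ok <- f$converged & !f$insensitive
    if (sum(!ok) > 0.5 * n_cells) {
      stop(sprintf("model class '%s' failed for more than half the cells",
                   nm), call. = FALSE)
    }
    p <- length(model_par_names(classes[[nm]]))
    bics <- p * log(f$n_trials[ok]) + 2 * f$nll[ok]
    data.frame(
      class = nm, n_params = p,
      mean_bic = mean(bics), se_bic = stats::sd(bics) / sqrt(sum(ok)),
      mean_pseudo_r2 = mean(f$pseudo_r2[ok]),
      n_well_described = sum(f$pseudo_r2[ok] >= well_described_r2),
      n_failed = sum(!ok)
    )
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$mean_bic, tab$n_params)
  best <- tab$mean_bic[ord[1]]
  tied <- which(abs(tab$mean_bic - best) < 1e-9)
  selected <- tab$class[tied[which.min(tab$n_params[tied])]]
  structure(list(table = tab, selected = selected, fits = fits),
            class = "dd_model_comparison")
}

#' @export
print.dd_model_comparison <- function(x, ...) {
  cat("<dd_model_comparison> selected:", x$selected, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
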
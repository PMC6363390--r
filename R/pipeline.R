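#' Simulate a cohort and write it to disk
#'
#' Writes the trial table as CSV and the generating configuration and
#' agent parameters ("truth") as JSON into `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param pop A [population_config()].
#' @param schedules Optional named list of [schedule_config()]s.
#' @param spec Generating [model_spec()].
#' @param seed Integer seed.
#' @return The simulated `dd_trials`, invisibly. Files written:
#'   `trials.csv`, `truth.json`.
#' @export
run_simulate <- function(out_dir, pop = population_config(),
                         schedules = NULL, spec = model_spec(), seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials <- simulate_cohort(pop, schedules = schedules, spec = spec,
                            seed = seed)
  write_trials(trials, file.path(out_dir, "trials.csv"))
  truth <- list(
    seed = seed,
    model = list(utility = spec$utility, choice_rule = spec$choice_rule),
    population = list(
      n_subjects = pop$n_subjects, tasks = pop$tasks,
      mean_logk = as.list(pop$mean_logk), sd_logk = as.list(pop$sd_logk),
      cross_task_correlation = pop$cross_task_correlation,
      mean_tau = as.list(pop$mean_tau), sd_log_tau = pop$sd_log_tau,
      mean_rho = as.list(pop$mean_rho), sd_log_rho = as.list(pop$sd_log_rho)),
    agents = cohort_truth(trials))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(trials)
}

#' Rebuild a population configuration from a truth file
#'
#' @param path Path to a `truth.json` written by [run_simulate()].
#' @return A [population_config()].
#' @export
read_truth_population <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- truth$population
  population_config(
    n_subjects = p$n_subjects, tasks = p$tasks,
    mean_logk = unlist(p$mean_logk), sd_logk = unlist(p$sd_logk),
    cross_task_correlation = matrix(unlist(p$cross_task_correlation),
                                    length(p$tasks), length(p$tasks)),
    mean_tau = unlist(p$mean_tau), sd_log_tau = p$sd_log_tau,
    mean_rho = unlist(p$mean_rho), sd_log_rho = unlist(p$sd_log_rho))
}

#' Fit a dataset and optionally persist the artifacts
#'
#' Runs the per-subject MLE, the hierarchical model, or both, after the
#' standard preparation filters.
#'
#' @param trials A trial table (or path to a trials CSV).
#' @param method `"mle"`, `"hierarchical"`, or `"both"`.
#' @param spec [model_spec()] for the MLE route.
#' @param config [hier_config()] for the hierarchical route.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param prepare Apply [prepare_dataset()] first (default TRUE).
#' @return List with elements `mle` (cohort estimate table) and/or
#'   `hierarchical` (`dd_posterior`), plus `trials` (the prepared table).
#' @export
run_fit <- function(trials, method = c("mle", "hierarchical", "both"),
                    spec = model_spec(), config = hier_config(),
                    out_dir = NULL, prepare = TRUE) {
  method <- match.arg(method)
  if (is.character(trials)) {
    if (!file.exists(trials)) stop("no such file: ", trials, call. = FALSE)
    trials <- read_trials(trials)
  }
  if (prepare) trials <- prepare_dataset(trials)
  out <- list(trials = trials)
  if (method %in% c("mle", "both")) {
    out$mle <- fit_cohort_mle(trials, spec = spec)
  }
  if (method %in% c("hierarchical", "both")) {
    out$hierarchical <- fit_hierarchical(trials, config)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(out$mle)) {
      utils::write.csv(out$mle, file.path(out_dir, "mle_estimates.csv"),
                       row.names = FALSE)
    }
    if (!is.null(out$hierarchical)) {
      h <- out$hierarchical
      utils::write.csv(h$subject_logk,
                       file.path(out_dir, "subject_logk.csv"),
                       row.names = FALSE)
      manifest <- list(
        tasks = h$tasks, n_subjects = length(h$subjects),
        seed = h$config$seed, chains = h$config$chains,
        draws_per_chain = h$config$draws,
        reward_scaling = h$config$reward_scaling,
        max_rhat = h$diagnostics$max_rhat,
        min_n_eff = h$diagnostics$min_n_eff,
        converged = h$converged)
      jsonlite::write_json(manifest, file.path(out_dir, "fit_manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  out
}

# wide subjid x task table of logk estimates from an MLE table or the
# subject_logk table of a hierarchical fit
logk_wide <- function(est) {
  est <- est[!is.na(est$logk), c("subjid", "task", "logk")]
  wide <- stats::reshape(est, idvar = "subjid", timevar = "task",
                         direction = "wide")
  names(wide) <- sub("^logk\\.", "", names(wide))
  row.names(wide) <- NULL
  wide
}

#' Assemble a reliability and context report
#'
#' From fitted per-subject log(k) estimates, builds cross-task Pearson and
#' Spearman correlations with intervals, pairwise dependent-correlation
#' tests, model-free fraction-later correlations, and (when exactly two
#' tasks are flagged for it and a hierarchical fit is supplied) the
#' adaptation analysis. Sections that need more subjects than available
#' are flagged rather than failing.
#'
#' @param trials The (prepared) trial table.
#' @param estimates Per subject-task logk table: the `mle` element of
#'   [run_fit()] or the `subject_logk` element of a `dd_posterior`.
#' @param posterior Optional `dd_posterior` for shift/scale evidence ratios.
#' @param out_dir Optional directory; writes `report.json`.
#' @param min_n Minimum subjects for correlation sections (default 4).
#' @param seed Integer seed for bootstrap intervals.
#' @return A `dd_report` list.
#' @export
run_report <- function(trials, estimates, posterior = NULL, out_dir = NULL,
                       min_n = 4, seed = 1) {
  wide <- logk_wide(estimates)
  tasks <- setdiff(names(wide), "subjid")
  report <- list(tasks = tasks, n_subjects = nrow(wide), flags = character())
  pairs <- utils::combn(tasks, 2, simplify = FALSE)
  cors <- list()
  for (pr in pairs) {
    ok <- stats::complete.cases(wide[, pr])
    nm <- paste(pr, collapse = "_vs_")
    if (sum(ok) < min_n) {
      report$flags <- c(report$flags,
                        sprintf("correlation %s: insufficient n (%d)", nm,
                                sum(ok)))
      next
    }
    x <- wide[ok, pr[1]]; y <- wide[ok, pr[2]]
    cors[[nm]] <- list(
      pearson = correlation_with_ci(x, y, "pearson"),
      spearman = correlation_with_ci(x, y, "spearman", n_boot = 2000,
                                     seed = seed))
  }
  report$correlations <- cors
  if (length(tasks) == 3 && nrow(wide) >= 10 &&
      all(stats::complete.cases(wide[, tasks]))) {
    r <- stats::cor(wide[, tasks])
    report$correlation_differences <- compare_dependent_correlations(
      r[tasks[1], tasks[2]], r[tasks[1], tasks[3]], r[tasks[2], tasks[3]],
      n = nrow(wide))
  }
  # model-free ranking check: fraction later per subject-task
  df <- as.data.frame(trials)
  fl <- stats::aggregate(chose_later ~ subjid + task, data = df, FUN = mean)
  names(fl)[3] <- "fraction_later"
  report$fraction_later <- fl
  if (!is.null(posterior) && posterior$converged) {
    report$shift_scale <- shift_scale_report(posterior)
  }
  class(report) <- "dd_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.dd_report <- function(x, ...) {
  cat(sprintf("<dd_report> %d subjects, tasks: %s\n", x$n_subjects,
              paste(x$tasks, collapse = ", ")))
  for (nm in names(x$correlations)) {
    p <- x$correlations[[nm]]$pearson
    cat(sprintf("  %s: Pearson r = %.2f [%.2f, %.2f]\n", nm, p$r,
                p$ci[1], p$ci[2]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
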
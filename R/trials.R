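DD_TRIAL_COLS <- c("subjid", "task", "session", "block", "trial",
                   "sooner_mag", "later_mag", "later_delay", "delay_unit",
                   "chose_later")

#' Construct a validated trial table
#'
#' A trial table is a data frame with one row per choice: subject, task,
#' session, block, 1-based trial index within (subject, task), the offer
#' (sooner magnitude at delay zero vs. later magnitude at a positive delay
#' in the task's native unit), and the boolean outcome `chose_later`.
#' Filters applied to the table are recorded append-only in a `provenance`
#' attribute.
#'
#' @param df Data frame with columns `subjid`, `task`, `session`, `block`,
#'   `trial`, `sooner_mag`, `later_mag`, `later_delay`, `delay_unit`,
#'   `chose_later`.
#' @param provenance List of provenance records (kept as-is).
#' @return A `dd_trials` data frame.
#' @export
dd_trials <- function(df, provenance = list()) {
  missing <- setdiff(DD_TRIAL_COLS, names(df))
  if (length(missing) > 0) {
    stop("trial table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[, DD_TRIAL_COLS]
  df$subjid <- as.character(df$subjid)
  df$task <- as.character(df$task)
  df$session <- as.integer(df$session)
  df$block <- as.integer(df$block)
  df$trial <- as.integer(df$trial)
  df$chose_later <- coerce_logical(df$chose_later)
  validate_trials(df)
  structure(df, provenance = provenance,
            class = c("dd_trials", "data.frame"))
}

coerce_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1, NA))) {
      stop("chose_later must be boolean (0/1)", call. = FALSE)
    }
    return(x == 1)
  }
  xl <- tolower(as.character(x))
  out <- rep(NA, length(xl))
  out[xl %in% c("1", "true", "t")] <- TRUE
  out[xl %in% c("0", "false", "f")] <- FALSE
  if (anyNA(out) && !anyNA(x)) {
    stop("chose_later must be boolean (0/1)", call. = FALSE)
  }
  out
}

validate_trials <- function(df) {
  bad_task <- setdiff(unique(df$task), DD_TASKS)
  if (length(bad_task) > 0) {
    stop("unknown task token(s): ", paste(bad_task, collapse = ", "),
         call. = FALSE)
  }
  bad_unit <- setdiff(unique(df$delay_unit), DD_UNITS)
  if (length(bad_unit) > 0) {
    stop("unknown delay unit(s): ", paste(bad_unit, collapse = ", "),
         call. = FALSE)
  }
  expected <- task_delay_unit(df$task)
  if (any(df$delay_unit != expected)) {
    i <- which(df$delay_unit != expected)[1]
    stop(sprintf("task %s expects delays in %ss, got %ss",
                 df$task[i], expected[i], df$delay_unit[i]), call. = FALSE)
  }
  if (any(df$later_delay <= 0)) stop("later_delay must be > 0", call. = FALSE)
  if (any(df$later_mag <= 0) || any(df$sooner_mag <= 0)) {
    stop("magnitudes must be > 0", call. = FALSE)
  }
  dup <- duplicated(df[, c("subjid", "task", "trial")])
  if (any(dup)) {
    stop("trial index must be unique within (subject, task)", call. = FALSE)
  }
  invisible(df)
}

#' Provenance of a trial table
#'
#' @param trials A `dd_trials` table.
#' @return The append-only list of filter records attached to the table.
#' @export
provenance <- function(trials) {
  attr(trials, "provenance") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

add_provenance <- function(trials, record) {
  prov <- c(provenance(trials), list(record))
  attr(trials, "provenance") <- prov
  trials
}

# Subsetting a dd_trials keeps class and provenance.
#' @export
`[.dd_trials` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(DD_TRIAL_COLS %in% names(out))) {
    structure(out, provenance = provenance(x),
              class = c("dd_trials", "data.frame"))
  } else {
    out
  }
}

#' Read a trial table from CSV
#'
#' Comma-separated UTF-8 with a header; `chose_later` encoded 0/1. Column
#' names and order as in [dd_trials()]. Unknown task or unit tokens raise a
#' validation error naming the offending value; missing columns raise a
#' format error naming the column.
#'
#' @param path Path to the CSV file.
#' @return A `dd_trials` table.
#' @seealso [write_trials()]
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dd_trials(df)
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trials()]: booleans written as 0/1, no row names. The
#' round-trip is lossless on all columns.
#'
#' @param trials A `dd_trials` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  df <- as.data.frame(trials)[, DD_TRIAL_COLS]
  df$chose_later <- as.integer(df$chose_later)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count first-order stochastic-dominance violations
#'
#' A smaller-later offer (later magnitude below the sooner magnitude) is
#' dominated by the immediate option; choosing it is a first-order
#' violation. Counts such choices per subject and session.
#'
#' @param trials A trial table.
#' @return Data frame with columns `subjid`, `session`, `n_violations`,
#'   `n_smaller_later` (number of dominated offers presented).
#' @export
count_first_order_violations <- function(trials) {
  if (nrow(trials) == 0) {
    return(data.frame(subjid = character(), session = integer(),
                      n_violations = integer(), n_smaller_later = integer()))
  }
  sl <- trials$later_mag < trials$sooner_mag
  viol <- sl & trials$chose_later
  agg <- stats::aggregate(
    cbind(n_violations = viol, n_smaller_later = sl),
    by = list(subjid = trials$subjid, session = trials$session),
    FUN = sum
  )
  agg$n_violations <- as.integer(agg$n_violations)
  agg$n_smaller_later <- as.integer(agg$n_smaller_later)
  agg[order(agg$subjid, agg$session), , drop = FALSE]
}

#' Flag subjects whose choices are insensitive to the offers
#'
#' A subject-task cell is flagged when the subject chose the later option on
#' all trials or on none (fraction later exactly 0 or 1), in which case the
#' discount rate is not identified.
#'
#' @param trials A trial table.
#' @return Data frame with columns `subjid`, `task`, `fraction_later`,
#'   `insensitive`.
#' @export
flag_insensitive_subjects <- function(trials) {
  agg <- stats::aggregate(chose_later ~ subjid + task,
                          data = as.data.frame(trials), FUN = mean)
  names(agg)[3] <- "fraction_later"
  agg$insensitive <- agg$fraction_later %in% c(0, 1)
  agg[order(agg$subjid, agg$task), , drop = FALSE]
}

#' Apply the standard data-preparation filters
#'
#' Drops first-session non-verbal trials (learning effects and elevated
#' first-order violation rates make them unsuitable for model fitting) and
#' flags -- optionally excludes -- subjects whose choices were insensitive
#' to the offers in some task (always-later or always-sooner). Each applied
#' filter is recorded in the table's provenance. Applying the same policy
#' twice is a no-op.
#'
#' @param trials A trial table.
#' @param drop_nv_session1 Drop NV trials from the first NV session
#'   (default `TRUE`).
#' @param exclude_insensitive Remove flagged subjects entirely
#'   (default `FALSE`; they are flagged either way).
#' @return A filtered `dd_trials` table; the insensitivity flags are stored
#'   in the provenance record.
#' @export
prepare_dataset <- function(trials, drop_nv_session1 = TRUE,
                            exclude_insensitive = FALSE) {
  out <- trials
  if (drop_nv_session1) {
    nv_sessions <- unique(out$session[out$task == "NV"])
    # session labels follow the study layout (NV sessions start at 1), so
    # dropping by label -- not by minimum -- keeps the filter idempotent
    drop <- out$task == "NV" & out$session == 1L & length(nv_sessions) > 1
    out <- out[!drop, , drop = FALSE]
    out <- add_provenance(out, list(
      filter = "drop_nv_session1",
      session = if (any(drop)) 1L else NA_integer_,
      n_dropped = sum(drop)))
  }
  flags <- flag_insensitive_subjects(out)
  bad_subj <- unique(flags$subjid[flags$insensitive])
  if (exclude_insensitive && length(bad_subj) > 0) {
    out <- out[!(out$subjid %in% bad_subj), , drop = FALSE]
  }
  out <- add_provenance(out, list(
    filter = "insensitive_subjects",
    flagged = bad_subj,
    excluded = isTRUE(exclude_insensitive)))
  if (nrow(out) == 0) {
    stop("no data left after filtering", call. = FALSE)
  }
  row.names(out) <- NULL
  out
}

#' Fraction of trials on which the later option was chosen
#'
#' A model-free impulsivity summary: the mean of `chose_later`. Ranking
#' subjects by this fraction gives a model-free counterpart to ranking by
#' fitted discount rates.
#'
#' @param trials A trial table (or any data frame with `chose_later`).
#' @return Proportion in `[0, 1]`.
#' @export
fraction_later <- function(trials) {
  if (nrow(trials) == 0) stop("no trials", call. = FALSE)
  mean(trials$chose_later)
}
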
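#' Unit and scaling constants used throughout the package
#'
#' A single surface for the fixed conversion constants: seconds per day
#' (86400), days per week (7), and the magnitude-effect factor (2) used when
#' moving discount rates from a large-stake to a small-stake reward scale.
#'
#' @return A named list with elements `seconds_per_day`, `days_per_week`,
#'   and `magnitude_factor`.
#' @examples
#' dd_constants()$seconds_per_day
#' @export
dd_constants <- function() {
  list(
    seconds_per_day = 86400,
    days_per_week = 7,
    magnitude_factor = 2
  )
}

# Task tokens and the delay unit each task uses. NV/SV run in seconds,
# LV/DV in days, WV in weeks.
DD_TASKS <- c("NV", "SV", "LV", "DV", "WV")
DD_UNITS <- c("second", "day", "week")

DD_TASK_UNIT <- c(
  NV = "second", SV = "second",
  LV = "day", DV = "day",
  WV = "week"
)

#' Delay unit native to a task
#'
#' @param task Character vector of task tokens (`NV`, `SV`, `LV`, `DV`, `WV`).
#' @return Character vector of delay units (`second`, `day`, `week`).
#' @examples
#' task_delay_unit(c("NV", "LV", "WV"))
#' @export
task_delay_unit <- function(task) {
  bad <- setdiff(unique(task), DD_TASKS)
  if (length(bad) > 0) {
    stop("unknown task token(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(DD_TASK_UNIT[task])
}
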
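#' Specify a discounting model class
#'
#' A model class pairs a utility family (hyperbolic or exponential) with a
#' choice rule (shift-invariant softmax or scale-invariant matching), and
#' optionally adds a utility-curvature exponent and a reward-scaling factor.
#' Parameters are fit on unconstrained scales: log(k) directly, and decision
#' noise tau, curvature alpha and reward scaling rho through log-links.
#'
#' @param utility `"hyperbolic"` or `"exponential"`.
#' @param choice_rule `"softmax"` or `"matching"`.
#' @param curvature Logical; if `TRUE`, magnitudes enter as `V^alpha` with a
#'   free per-subject exponent `alpha > 0`.
#' @param reward_scaling Logical; if `TRUE`, magnitudes are multiplied by a
#'   free scaling factor `rho > 0` before the utility transform.
#' @return An object of class `dd_model_spec`.
#' @examples
#' model_spec()                       # softmax-hyperbolic, the default class
#' model_spec("exponential", "matching")
#' @export
model_spec <- function(utility = c("hyperbolic", "exponential"),
                       choice_rule = c("softmax", "matching"),
                       curvature = FALSE,
                       reward_scaling = FALSE) {
  utility <- match.arg(utility)
  choice_rule <- match.arg(choice_rule)
  stopifnot(is.logical(curvature), length(curvature) == 1L,
            is.logical(reward_scaling), length(reward_scaling) == 1L)
  spec <- list(
    utility = utility,
    choice_rule = choice_rule,
    curvature = curvature,
    reward_scaling = reward_scaling
  )
  class(spec) <- "dd_model_spec"
  spec
}

#' @export
print.dd_model_spec <- function(x, ...) {
  extras <- c(if (x$curvature) "curvature" else NULL,
              if (x$reward_scaling) "reward scaling" else NULL)
  cat(sprintf("<dd_model_spec> %s utility, %s rule%s\n",
              x$utility, x$choice_rule,
              if (length(extras)) paste0(" + ", paste(extras, collapse = " + ")) else ""))
  invisible(x)
}

#' Names of free parameters of a model class
#'
#' @param spec A [model_spec()].
#' @return Character vector of parameter names on the unconstrained
#'   (link) scale, e.g. `c("logk", "log_tau")`.
#' @export
model_par_names <- function(spec) {
  stopifnot(inherits(spec, "dd_model_spec"))
  c("logk", "log_tau",
    if (spec$curvature) "log_alpha" else NULL,
    if (spec$reward_scaling) "log_rho" else NULL)
}

#' The four standard model classes
#'
#' Convenience constructor for the four utility-family by choice-rule
#' combinations considered in model comparison.
#'
#' @return Named list of four [model_spec()] objects.
#' @export
standard_model_classes <- function() {
  list(
    "hyperbolic-softmax"   = model_spec("hyperbolic", "softmax"),
    "exponential-softmax"  = model_spec("exponential", "softmax"),
    "hyperbolic-matching"  = model_spec("hyperbolic", "matching"),
    "exponential-matching" = model_spec("exponential", "matching")
  )
}
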
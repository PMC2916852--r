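#' Model parameters for the causal-inference observer
#'
#' Bundles the four free parameters of the audiovisual causal-inference
#' model, plus the selection criterion used by the model-selection strategy.
#'
#' @param sigma_A Auditory likelihood standard deviation, degrees (> 0).
#' @param sigma_V Visual likelihood standard deviation, degrees (> 0).
#' @param sigma_P Standard deviation of the Gaussian spatial prior, degrees
#'   (> 0). The prior mean is fixed at 0 degrees (straight ahead).
#' @param p_common Prior probability of a common cause, in \[0, 1\].
#' @param criterion Posterior threshold used by the model-selection strategy.
#'   The standard (unbiased) model chooses the common-cause estimates when the
#'   posterior probability of a common cause exceeds 0.5; the biased variant
#'   frees this threshold as a fifth parameter.
#'
#' @return An object of class `"model_params"`: a named list with the five
#'   fields above.
#'
#' @examples
#' model_params(sigma_A = 10.1, sigma_V = 2.5, sigma_P = 33, p_common = 0.57)
#' @export
model_params <- function(sigma_A, sigma_V, sigma_P, p_common,
                         criterion = 0.5) {
  p <- structure(
    list(sigma_A = as.numeric(sigma_A), sigma_V = as.numeric(sigma_V),
         sigma_P = as.numeric(sigma_P), p_common = as.numeric(p_common),
         criterion = as.numeric(criterion)),
    class = "model_params")
  validate_params(p)
  p
}

validate_params <- function(params) {
  stopifnot(inherits(params, "model_params") || is.list(params))
  with(params, {
    if (!is.finite(sigma_A) || sigma_A <= 0) stop("sigma_A must be > 0")
    if (!is.finite(sigma_V) || sigma_V <= 0) stop("sigma_V must be > 0")
    if (!is.finite(sigma_P) || sigma_P <= 0) stop("sigma_P must be > 0")
    if (!is.finite(p_common) || p_common < 0 || p_common > 1)
      stop("p_common must lie in [0, 1]")
    if (!is.finite(criterion) || criterion < 0 || criterion > 1)
      stop("criterion must lie in [0, 1]")
  })
  invisible(params)
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "causal-inference model parameters:\n  sigma_A = %.3g deg, sigma_V = %.3g deg, sigma_P = %.3g deg\n  p_common = %.3g, selection criterion = %.3g\n",
    x$sigma_A, x$sigma_V, x$sigma_P, x$p_common, x$criterion))
  invisible(x)
}

#' Mean-subject parameter set
#'
#' The parameter values typical of fitted human observers in this task
#' (visual noise 2.5 degrees, auditory noise 10.1 degrees, spatial-prior SD
#' 33.0 degrees, prior probability of a common cause 0.57). Used as the
#' default generating parameters for synthetic observers and simulations.
#'
#' @return A [model_params()] object.
#' @export
mean_subject_params <- function() {
  model_params(sigma_A = 10.1, sigma_V = 2.5, sigma_P = 33.0,
               p_common = 0.57)
}

#' The three decision strategies
#'
#' @return Character vector `c("averaging", "selection", "matching")`.
#' @export
strategies <- function() c("averaging", "selection", "matching")

match_strategy <- function(strategy) {
  match.arg(strategy, strategies())
}

# integer codes shared with the compiled likelihood path
strategy_code <- function(strategy) {
  match(match_strategy(strategy), strategies()) - 1L
}
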
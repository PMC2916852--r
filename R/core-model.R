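#' Log-likelihood of the sensations under a common cause
#'
#' Joint density of a pair of noisy sensations `(x_A, x_V)` given that a
#' single source produced both, with the source location marginalized over
#' the central Gaussian prior. The marginal integral has the closed form
#' \deqn{p(x_A, x_V \mid C=1) =
#'   \frac{1}{2\pi\sqrt{\sigma_A^2\sigma_V^2 + \sigma_A^2\sigma_P^2 +
#'   \sigma_V^2\sigma_P^2}}
#'   \exp\left(-\tfrac12 \frac{(x_A-x_V)^2\sigma_P^2 + x_A^2\sigma_V^2 +
#'   x_V^2\sigma_A^2}{\sigma_A^2\sigma_V^2 + \sigma_A^2\sigma_P^2 +
#'   \sigma_V^2\sigma_P^2}\right).}
#'
#' Computation is carried out in log space so that large audiovisual
#' discrepancies do not underflow.
#'
#' @param x_A,x_V Sensations (noisy internal location measurements), degrees
#'   azimuth. Vectorized.
#' @param params A [model_params()] object.
#' @param log Return the log density (default `FALSE`).
#' @return Density (or log density) values, strictly positive and finite.
#' @seealso [likelihood_c2()], [posterior_c1()]
#' @export
likelihood_c1 <- function(x_A, x_V, params, log = FALSE) {
  validate_params(params)
  v_A <- params$sigma_A^2; v_V <- params$sigma_V^2; v_P <- params$sigma_P^2
  vsum <- v_A * v_V + v_A * v_P + v_V * v_P
  ll <- -log(2 * pi) - 0.5 * log(vsum) -
    0.5 * ((x_A - x_V)^2 * v_P + x_A^2 * v_V + x_V^2 * v_A) / vsum
  if (log) ll else exp(ll)
}

#' Log-likelihood of the sensations under independent causes
#'
#' Joint density of `(x_A, x_V)` given two independent sources, each drawn
#' from the central spatial prior. The density factorizes into auditory and
#' visual marginals: `N(x_A; 0, sigma_A^2 + sigma_P^2) * N(x_V; 0,
#' sigma_V^2 + sigma_P^2)`.
#'
#' @inheritParams likelihood_c1
#' @return Density (or log density) values.
#' @export
likelihood_c2 <- function(x_A, x_V, params, log = FALSE) {
  validate_params(params)
  ll <- dnorm(x_A, 0, sqrt(params$sigma_A^2 + params$sigma_P^2), log = TRUE) +
    dnorm(x_V, 0, sqrt(params$sigma_V^2 + params$sigma_P^2), log = TRUE)
  if (log) ll else exp(ll)
}

#' Posterior probability of a common cause
#'
#' Bayes' rule over the two causal structures:
#' `post = L1 * pc / (L1 * pc + L2 * (1 - pc))`, where `L1`, `L2` are the
#' sensation likelihoods under the common-cause and independent-cause
#' structures and `pc` is the prior probability of a common cause.
#' Evaluated in log space.
#'
#' @inheritParams likelihood_c1
#' @return Posterior probabilities in \[0, 1\].
#' @export
posterior_c1 <- function(x_A, x_V, params) {
  validate_params(params)
  pc <- params$p_common
  if (pc == 0) return(rep(0, length(x_A + x_V)))
  if (pc == 1) return(rep(1, length(x_A + x_V)))
  l1 <- likelihood_c1(x_A, x_V, params, log = TRUE)
  l2 <- likelihood_c2(x_A, x_V, params, log = TRUE)
  # logistic of the log posterior odds
  plogis_(log(pc) - log1p(-pc) + l1 - l2)
}

plogis_ <- function(z) 1 / (1 + exp(-z))

#' Fused location estimate under the common-cause structure
#'
#' Precision-weighted combination of both sensations and the central prior:
#' `(x_A/sigma_A^2 + x_V/sigma_V^2 + 0/sigma_P^2) /
#'  (1/sigma_A^2 + 1/sigma_V^2 + 1/sigma_P^2)`.
#' This is the posterior mean (= mode) of the source location given `C = 1`,
#' and is reported for both modalities.
#'
#' @inheritParams likelihood_c1
#' @return Location estimates, degrees.
#' @export
estimate_c1 <- function(x_A, x_V, params) {
  validate_params(params)
  if (missing(x_A) || missing(x_V) || any(is.na(x_A)) || any(is.na(x_V)))
    stop("estimate_c1() requires both sensations")
  w_A <- 1 / params$sigma_A^2; w_V <- 1 / params$sigma_V^2
  w_P <- 1 / params$sigma_P^2
  (x_A * w_A + x_V * w_V) / (w_A + w_V + w_P)
}

#' Single-cue location estimate under independent causes
#'
#' Shrinkage of one sensation toward the prior mean (0 degrees):
#' `x * sigma_P^2 / (sigma_P^2 + sigma^2)`. Used with `sigma = sigma_A` for
#' the auditory sensation and `sigma = sigma_V` for the visual one, and also
#' on unisensory trials, where no causal inference is invoked.
#'
#' @param x Sensation, degrees. Vectorized.
#' @param sigma Likelihood SD of the relevant modality, degrees.
#' @param params A [model_params()] object (supplies `sigma_P`).
#' @return Shrunken location estimates, degrees.
#' @export
estimate_c2 <- function(x, sigma, params) {
  validate_params(params)
  if (any(is.na(x))) stop("estimate_c2() requires a sensation")
  x * params$sigma_P^2 / (params$sigma_P^2 + sigma^2)
}

#' Per-structure estimates and causal posterior for one or more trials
#'
#' Convenience bundle computing everything [apply_strategy()] needs from a
#' pair of sensations.
#'
#' @inheritParams likelihood_c1
#' @return An object of class `"structure_estimates"`: a list with vector
#'   fields `s_hat_A_c1`, `s_hat_V_c1` (identical by construction),
#'   `s_hat_A_c2`, `s_hat_V_c2`, and `post_c1`.
#' @export
structure_estimates <- function(x_A, x_V, params) {
  fused <- estimate_c1(x_A, x_V, params)
  structure(
    list(s_hat_A_c1 = fused,
         s_hat_V_c1 = fused,
         s_hat_A_c2 = estimate_c2(x_A, params$sigma_A, params),
         s_hat_V_c2 = estimate_c2(x_V, params$sigma_V, params),
         post_c1 = posterior_c1(x_A, x_V, params)),
    class = "structure_estimates")
}

#' Map per-structure estimates to a trial's final location reports
#'
#' The three decision strategies turn the causal posterior and the
#' per-structure location estimates into the reported auditory and visual
#' locations:
#' \describe{
#'   \item{averaging}{posterior-weighted average of the two structures'
#'     estimates (minimizes expected squared error).}
#'   \item{selection}{all-or-none: the common-cause estimates are used iff
#'     `post_c1 > criterion` (0.5 for the standard model; free in the
#'     biased variant), otherwise the independent-cause estimates.}
#'   \item{matching}{stochastic selection: the common-cause estimates are
#'     used iff `post_c1 > xi`, with `xi` drawn fresh from Uniform(0, 1) on
#'     each trial, so the common structure is chosen with probability equal
#'     to its posterior.}
#' }
#' For selection and matching a single structure choice governs both
#' modality reports on a trial. Ties (`post_c1` exactly equal to the
#' threshold) resolve to the independent-cause structure.
#'
#' @param strategy One of `"averaging"`, `"selection"`, `"matching"`.
#' @param est A [structure_estimates()] object (vectorized over trials).
#' @param params A [model_params()] object.
#' @param xi Uniform(0, 1) draw(s); required for `"matching"` only, one per
#'   trial.
#' @return A list with numeric vectors `s_hat_A` and `s_hat_V`, degrees.
#' @export
apply_strategy <- function(strategy, est, params, xi = NULL) {
  strategy <- match_strategy(strategy)
  validate_params(params)
  stopifnot(inherits(est, "structure_estimates"))
  post <- est$post_c1
  use_c1 <- switch(strategy,
    averaging = NULL,
    selection = post > params$criterion,
    matching = {
      if (is.null(xi)) stop("matching requires a uniform draw `xi`")
      stopifnot(length(xi) == length(post) || length(xi) == 1L)
      post > xi
    })
  if (strategy == "averaging") {
    list(s_hat_A = post * est$s_hat_A_c1 + (1 - post) * est$s_hat_A_c2,
         s_hat_V = post * est$s_hat_V_c1 + (1 - post) * est$s_hat_V_c2)
  } else {
    list(s_hat_A = ifelse(use_c1, est$s_hat_A_c1, est$s_hat_A_c2),
         s_hat_V = ifelse(use_c1, est$s_hat_V_c1, est$s_hat_V_c2))
  }
}

#' Expected accuracy of matching vs maximizing on a binary event
#'
#' For a binary event that occurs with probability `p`, always predicting
#' the more likely outcome is correct with probability `max(p, 1 - p)`,
#' whereas predicting each outcome with probability equal to its frequency
#' (probability matching) is correct with probability `p^2 + (1 - p)^2`.
#'
#' @param p Probability of the more likely outcome, in \[0, 1\].
#' @return Named vector with elements `matching` and `maximizing`.
#' @examples
#' binary_prediction_accuracy(0.70)  # matching 0.58, maximizing 0.70
#' @export
binary_prediction_accuracy <- function(p) {
  stopifnot(p >= 0, p <= 1)
  c(matching = p^2 + (1 - p)^2, maximizing = max(p, 1 - p))
}
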
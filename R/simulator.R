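#' Sample noisy sensations for a stimulus condition
#'
#' Each presented stimulus produces an internal sensation corrupted by
#' independent Gaussian noise: `x_A ~ N(s_A, sigma_A^2)`,
#' `x_V ~ N(s_V, sigma_V^2)`. Absent modalities yield `NA`.
#'
#' @param cond A list or one-row data frame with `s_A` and `s_V` (degrees;
#'   `NA` when that modality is absent).
#' @param params A [model_params()] object.
#' @param n Number of trials to sample.
#' @param seed Integer seed; identical seeds give identical streams.
#' @return A data frame with columns `x_A`, `x_V` (`n` rows).
#' @export
sample_sensations <- function(cond, params, n, seed = 1) {
  validate_params(params)
  stopifnot(n >= 1)
  has_A <- !is.null(cond$s_A) && !is.na(cond$s_A)
  has_V <- !is.null(cond$s_V) && !is.na(cond$s_V)
  if (!has_A && !has_V) stop("condition must present at least one stimulus")
  with_seed(seed, {
    x_A <- if (has_A) rnorm(n, cond$s_A, params$sigma_A) else rep(NA_real_, n)
    x_V <- if (has_V) rnorm(n, cond$s_V, params$sigma_V) else rep(NA_real_, n)
    data.frame(x_A = x_A, x_V = x_V)
  })
}

#' Turn sensations into responses under a decision strategy (vectorized)
#'
#' Reference implementation of the full generative response process: for
#' bisensory trials, per-structure estimates and the causal posterior feed
#' the chosen strategy; unisensory trials use single-cue shrinkage of the
#' available sensation.
#'
#' @param trials Data frame with columns `cond_type` (`"A"`, `"V"`, `"AV"`),
#'   `s_A`, `s_V` (degrees, `NA` when absent).
#' @param params A [model_params()] object.
#' @param strategy One of [strategies()].
#' @param z_A,z_V Standard-normal noise draws, one per trial (used where the
#'   modality is present).
#' @param xi Uniform(0, 1) draws, one per trial (used by matching on
#'   bisensory trials).
#' @return The `trials` data frame with `resp_A`, `resp_V` columns added
#'   (`NA` for absent modalities).
#' @export
simulate_trial_responses <- function(trials, params, strategy, z_A, z_V, xi) {
  strategy <- match_strategy(strategy)
  validate_params(params)
  n <- nrow(trials)
  stopifnot(length(z_A) == n, length(z_V) == n, length(xi) == n)
  resp_A <- rep(NA_real_, n)
  resp_V <- rep(NA_real_, n)

  uni_A <- trials$cond_type == "A"
  uni_V <- trials$cond_type == "V"
  bis <- trials$cond_type == "AV"

  if (any(uni_A)) {
    x <- trials$s_A[uni_A] + params$sigma_A * z_A[uni_A]
    resp_A[uni_A] <- estimate_c2(x, params$sigma_A, params)
  }
  if (any(uni_V)) {
    x <- trials$s_V[uni_V] + params$sigma_V * z_V[uni_V]
    resp_V[uni_V] <- estimate_c2(x, params$sigma_V, params)
  }
  if (any(bis)) {
    x_A <- trials$s_A[bis] + params$sigma_A * z_A[bis]
    x_V <- trials$s_V[bis] + params$sigma_V * z_V[bis]
    est <- structure_estimates(x_A, x_V, params)
    out <- apply_strategy(strategy, est, params, xi = xi[bis])
    resp_A[bis] <- out$s_hat_A
    resp_V[bis] <- out$s_hat_V
  }
  trials$resp_A <- resp_A
  trials$resp_V <- resp_V
  trials
}

#' Default azimuth grid for binned response distributions
#'
#' Bins of 0.1 degree spanning half the 134-degree screen on either side of
#' fixation, matching the apparatus response resolution.
#'
#' @param half_span Half-width of the grid, degrees.
#' @param bin_width Bin width, degrees.
#' @return A list with `lo`, `hi`, `bin_width`, `breaks`, `centers`.
#' @export
response_grid <- function(half_span = 67, bin_width = 0.1) {
  breaks <- seq(-half_span, half_span, by = bin_width)
  list(lo = -half_span, hi = half_span, bin_width = bin_width,
       breaks = breaks, centers = breaks[-length(breaks)] + bin_width / 2)
}

bin_index <- function(x, grid) {
  idx <- floor((x - grid$lo) / grid$bin_width) + 1L
  nb <- length(grid$centers)
  pmin.int(pmax.int(idx, 1L), nb)
}

bin_probs <- function(x, grid) {
  x <- x[!is.na(x)]
  tabulate(bin_index(x, grid), nbins = length(grid$centers)) / length(x)
}

#' Monte-Carlo response distribution for one stimulus condition
#'
#' Simulates `n` trials of a condition under one decision strategy and bins
#' the continuous responses on an azimuth grid, giving the model-predicted
#' response distribution for each presented modality.
#'
#' @inheritParams sample_sensations
#' @param strategy One of [strategies()].
#' @param grid A [response_grid()].
#' @return An object of class `"response_distribution"`: list with
#'   `condition`, `strategy`, `grid`, `n`, `seed`, and `p_A`, `p_V` (binned
#'   probabilities summing to 1, or `NULL` for an absent modality).
#' @examples
#' d <- simulate_condition(list(s_A = 13, s_V = -13), mean_subject_params(),
#'                         "selection", n = 2000, seed = 7)
#' sum(d$p_A)
#' @export
simulate_condition <- function(cond, params, strategy, n = 10000, seed = 1,
                               grid = response_grid()) {
  strategy <- match_strategy(strategy)
  validate_params(params)
  stopifnot(n >= 1)
  has_A <- !is.null(cond$s_A) && !is.na(cond$s_A)
  has_V <- !is.null(cond$s_V) && !is.na(cond$s_V)
  cond_type <- if (has_A && has_V) "AV" else if (has_A) "A" else "V"
  trials <- data.frame(
    cond_type = rep(cond_type, n),
    s_A = if (has_A) cond$s_A else NA_real_,
    s_V = if (has_V) cond$s_V else NA_real_)
  sim <- with_seed(seed, {
    simulate_trial_responses(trials, params, strategy,
                             z_A = rnorm(n), z_V = rnorm(n), xi = runif(n))
  })
  structure(
    list(condition = list(s_A = if (has_A) cond$s_A else NA_real_,
                          s_V = if (has_V) cond$s_V else NA_real_),
         strategy = strategy, grid = grid, n = n, seed = seed,
         p_A = if (has_A) bin_probs(sim$resp_A, grid) else NULL,
         p_V = if (has_V) bin_probs(sim$resp_V, grid) else NULL),
    class = "response_distribution")
}

#' Count modes of a binned response distribution
#'
#' Smooths the binned probabilities with a fixed-width Gaussian kernel and
#' counts local maxima by topographic prominence: a peak counts as a mode
#' only if it rises by at least `min_prominence` (relative to the global
#' maximum) above the deepest valley separating it from a taller accepted
#' peak. This suppresses both Monte-Carlo ripple and shoulders on broad
#' plateaus, and operationalizes the unimodal-vs-bimodal signature that
#' separates the averaging strategy from selection and matching.
#'
#' @param dist A [simulate_condition()] result.
#' @param modality `"A"` or `"V"`.
#' @param bandwidth Gaussian kernel SD, degrees (default 1.5, the scale of
#'   the visual stimulus envelope).
#' @param min_prominence Minimum peak prominence relative to the global
#'   maximum of the smoothed distribution (default 0.1).
#' @return Integer mode count, with attributes `bandwidth`,
#'   `min_prominence`, and `mode_locations` (degrees).
#' @export
bimodality_diagnostic <- function(dist, modality = "A", bandwidth = 1.5,
                                  min_prominence = 0.1) {
  stopifnot(inherits(dist, "response_distribution"))
  p <- if (modality == "A") dist$p_A else dist$p_V
  if (is.null(p) || length(p) == 0 || anyNA(p) || sum(p) == 0)
    stop("empty distribution")
  sm <- kernel_smooth(p, dist$grid$bin_width, bandwidth)
  n <- length(sm)
  left <- c(-Inf, sm[-n]); right <- c(sm[-1], -Inf)
  cand <- which(sm > left & sm >= right)
  if (length(cand) > 1) {  # collapse flat-top plateaus
    cand <- cand[c(TRUE, diff(cand) > 1L)]
  }
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  accepted <- integer(0)
  thr <- min_prominence * max(sm)
  for (i in cand) {
    if (length(accepted) == 0) {
      accepted <- i
      next
    }
    # deepest point between this peak and the nearest taller accepted peak
    nearest <- accepted[which.min(abs(accepted - i))]
    valley <- min(sm[seq(min(i, nearest), max(i, nearest))])
    if (sm[i] - valley >= thr) accepted <- c(accepted, i)
  }
  locs <- sort(dist$grid$centers[accepted])
  structure(length(locs), bandwidth = bandwidth,
            min_prominence = min_prominence, mode_locations = locs)
}

kernel_smooth <- function(p, bin_width, bandwidth) {
  half <- ceiling(4 * bandwidth / bin_width)
  k <- dnorm(seq(-half, half) * bin_width, sd = bandwidth)
  k <- k / sum(k)
  n <- length(p)
  padded <- c(rep(0, half), p, rep(0, half))
  vapply(seq_len(n),
         function(i) sum(padded[i:(i + 2 * half)] * k), numeric(1))
}
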
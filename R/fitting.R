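#' Fitting configuration
#'
#' Collects the knobs of the simulation-based likelihood and of the
#' multi-start optimizer. All values are recorded in fit results.
#'
#' @param mc_samples Monte-Carlo samples per condition used to build the
#'   predicted response distributions (default 10000).
#' @param bin_width Likelihood histogram bin width, degrees (default 1).
#' @param half_span Half-width of the response grid, degrees (default 67,
#'   half the screen).
#' @param prob_floor Probability floor applied per bin before
#'   renormalization, so empty bins contribute `log(floor)` rather than
#'   `-Inf` (default 1e-6).
#' @param restarts Number of optimizer starts (default 20): one data-driven
#'   start plus jittered/dispersed restarts.
#' @param maxit Nelder-Mead iteration cap per start (default 300).
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param seed Seed for the common random numbers: the same sensation and
#'   uniform draws are reused across optimizer iterations so the likelihood
#'   surface is deterministic for the optimizer.
#' @param bounds Named list of `c(lower, upper)` boxes for `sigma_A`,
#'   `sigma_V`, `sigma_P`, `p_common`, `criterion`.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(mc_samples = 10000, bin_width = 1, half_span = 67,
                       prob_floor = 1e-6, restarts = 20, maxit = 300,
                       reltol = 1e-7, seed = 1,
                       bounds = list(sigma_A = c(0.1, 45),
                                     sigma_V = c(0.1, 45),
                                     sigma_P = c(1, 200),
                                     p_common = c(0, 1),
                                     criterion = c(0, 1))) {
  stopifnot(mc_samples >= 1, restarts >= 1)
  structure(list(mc_samples = mc_samples, bin_width = bin_width,
                 half_span = half_span, prob_floor = prob_floor,
                 restarts = restarts, maxit = maxit, reltol = reltol,
                 seed = seed, bounds = bounds),
            class = "fit_config")
}

# --- data preparation ------------------------------------------------------

# Validate a subject dataset and index its conditions/observations against
# the likelihood grid. Observations falling outside the grid are clipped to
# the edge bins with a warning; the count is returned.
prepare_observations <- function(data, config) {
  need <- c("cond_type", "s_A", "s_V", "resp_A", "resp_V")
  if (!all(need %in% names(data))) {
    stop("dataset must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(data) == 0) stop("dataset is empty")
  bad_bis <- data$cond_type == "AV" &
    (is.na(data$resp_A) | is.na(data$resp_V))
  if (any(bad_bis)) {
    stop("bisensory trials missing a response at rows ",
         paste(utils::head(which(bad_bis), 5), collapse = ", "))
  }
  grid <- response_grid(config$half_span, config$bin_width)
  conds <- condition_table(data)
  key <- function(t, a, v) paste(t, a, v, sep = "|")
  cond_of <- match(key(data$cond_type, data$s_A, data$s_V),
                   key(conds$cond_type, conds$s_A, conds$s_V))

  obs_cond <- integer(0); obs_mod <- integer(0); obs_val <- numeric(0)
  has_a <- !is.na(data$resp_A); has_v <- !is.na(data$resp_V)
  obs_cond <- c(cond_of[has_a], cond_of[has_v])
  obs_mod <- c(rep(0L, sum(has_a)), rep(1L, sum(has_v)))
  obs_val <- c(data$resp_A[has_a], data$resp_V[has_v])

  outside <- obs_val < grid$lo | obs_val >= grid$hi
  if (any(outside)) {
    warning(sum(outside), " response(s) outside the likelihood grid; clipped")
  }
  list(grid = grid, conds = conds,
       obs_cond = obs_cond - 1L, obs_mod = obs_mod,
       obs_bin = bin_index(obs_val, grid) - 1L,
       n_clipped = sum(outside), n_responses = length(obs_val))
}

# Common random numbers shared across optimizer iterations.
draw_crn <- function(ncond, mc_samples, seed) {
  with_seed(seed, {
    n <- ncond * mc_samples
    list(samp_cond = rep(seq_len(ncond) - 1L, each = mc_samples),
         z_A = rnorm(n), z_V = rnorm(n), xi = runif(n))
  })
}

cond_type_code <- function(cond_type) {
  match(cond_type, c("A", "V", "AV")) - 1L
}

loglik_from_crn <- function(prep, crn, params, strategy) {
  cpp_mc_loglik(
    crn$samp_cond, cond_type_code(prep$conds$cond_type),
    as.numeric(prep$conds$s_A), as.numeric(prep$conds$s_V),
    crn$z_A, crn$z_V, crn$xi,
    params$sigma_A, params$sigma_V, params$sigma_P,
    params$p_common, params$criterion, strategy_code(strategy),
    prep$grid$lo, prep$grid$bin_width, length(prep$grid$centers),
    prep$obs_cond, prep$obs_mod, prep$obs_bin, prep$prob_floor)
}

#' Monte-Carlo log-likelihood of a subject's responses
#'
#' For each stimulus condition the model's predicted response distribution
#' is built by forward simulation (`mc_samples` draws), binned on the
#' response grid, floored and renormalized; the log-probabilities of the
#' subject's observed responses (both modality reports on bisensory trials)
#' are then summed. Deterministic given `seed`.
#'
#' @param data A subject dataset (columns `cond_type`, `s_A`, `s_V`,
#'   `resp_A`, `resp_V`).
#' @param params A [model_params()] object.
#' @param strategy One of [strategies()].
#' @param mc_samples Monte-Carlo samples per condition.
#' @param seed Seed for the sensation/uniform draws.
#' @param config A [fit_config()] supplying grid and floor settings.
#' @return The log-likelihood (finite scalar) with attributes `n_clipped`
#'   and `n_responses`.
#' @export
response_loglik <- function(data, params, strategy,
                            mc_samples = config$mc_samples,
                            seed = config$seed, config = fit_config()) {
  validate_params(params)
  strategy <- match_strategy(strategy)
  prep <- prepare_observations(data, config)
  prep$prob_floor <- config$prob_floor
  crn <- draw_crn(nrow(prep$conds), mc_samples, seed)
  ll <- loglik_from_crn(prep, crn, params, strategy)
  structure(ll, n_clipped = prep$n_clipped, n_responses = prep$n_responses)
}

# --- parameter transform ---------------------------------------------------

# Optimization runs unconstrained; a scaled logistic maps each coordinate
# into its box.
par_names <- function(free_criterion) {
  c("sigma_A", "sigma_V", "sigma_P", "p_common",
    if (free_criterion) "criterion")
}

to_box <- function(t, bounds, names) {
  p <- mapply(function(ti, nm) {
    b <- bounds[[nm]]
    b[1] + (b[2] - b[1]) * plogis_(ti)
  }, t, names)
  setNames(as.numeric(p), names)
}

from_box <- function(p, bounds, names) {
  t <- mapply(function(pi, nm) {
    b <- bounds[[nm]]
    u <- (pi - b[1]) / (b[2] - b[1])
    u <- min(max(u, 1e-4), 1 - 1e-4)
    log(u) - log1p(-u)
  }, p, names)
  as.numeric(t)
}

params_from_vector <- function(p, free_criterion) {
  model_params(sigma_A = p[["sigma_A"]], sigma_V = p[["sigma_V"]],
               sigma_P = p[["sigma_P"]], p_common = p[["p_common"]],
               criterion = if (free_criterion) p[["criterion"]] else 0.5)
}

# Moment-based starting values from the unisensory conditions: response SDs
# estimate the (shrunken) sensory noise, and the regression slope of mean
# auditory response on true location estimates the prior shrinkage factor
# sigma_P^2 / (sigma_P^2 + sigma_A^2).
initial_params_guess <- function(data, bounds) {
  clamp <- function(x, b) min(max(x, b[1] * 1.05), b[2] * 0.95)
  pooled_sd <- function(resp, loc) {
    if (length(resp) < 5) return(NA_real_)
    res <- resp - ave(resp, loc)
    max(sd(res), 0.3)
  }
  a <- data[data$cond_type == "A", ]
  v <- data[data$cond_type == "V", ]
  sdA <- pooled_sd(a$resp_A, a$s_A)
  sdV <- pooled_sd(v$resp_V, v$s_V)
  slope <- tryCatch({
    m <- tapply(a$resp_A, a$s_A, mean)
    unname(coef(lm(m ~ as.numeric(names(m))))[2])
  }, error = function(e) NA_real_)
  if (!is.finite(slope) || slope <= 0.05 || slope >= 0.98) slope <- 0.9
  sigma_A <- if (is.finite(sdA)) sdA / slope else 10
  sigma_V <- if (is.finite(sdV)) sdV else 2.5
  sigma_P <- sqrt(slope / (1 - slope)) * sigma_A
  c(sigma_A = clamp(sigma_A, bounds$sigma_A),
    sigma_V = clamp(sigma_V, bounds$sigma_V),
    sigma_P = clamp(sigma_P, bounds$sigma_P),
    p_common = 0.5, criterion = 0.5)
}

#' Fit one decision strategy to a subject by maximum likelihood
#'
#' Maximizes [response_loglik()] over the model parameters with a
#' multi-start bounded Nelder-Mead search (scaled-logistic box transform).
#' The first start is moment-based (unisensory response SDs and the central
#' bias slope); the remaining starts jitter it and disperse `p_common`.
#' Common random numbers keep the objective deterministic across
#' iterations.
#'
#' @param data Subject dataset.
#' @param strategy One of [strategies()].
#' @param config A [fit_config()].
#' @param free_criterion If `TRUE`, fit the biased model-selection variant
#'   with the posterior threshold as a fifth free parameter (only
#'   meaningful for `strategy = "selection"`).
#' @return An object of class `"fit_result"`: list with `strategy`,
#'   `params`, `loglik`, `n_responses`, `n_clipped`, `free_criterion`,
#'   `n_par`, `diagnostics` (per-start values and convergence codes) and
#'   `config`.
#' @export
fit_strategy <- function(data, strategy, config = fit_config(),
                         free_criterion = FALSE) {
  strategy <- match_strategy(strategy)
  prep <- prepare_observations(data, config)
  prep$prob_floor <- config$prob_floor
  crn <- draw_crn(nrow(prep$conds), config$mc_samples, config$seed)
  nms <- par_names(free_criterion)

  objective <- function(t) {
    p <- to_box(t, config$bounds, nms)
    -loglik_from_crn(prep, crn, params_from_vector(p, free_criterion),
                     strategy)
  }

  guess <- initial_params_guess(data, config$bounds)[nms]
  t0 <- from_box(guess, config$bounds, nms)
  starts <- list(t0)
  extra <- config$restarts - 1L
  if (extra > 0) {
    jit <- with_seed(config$seed + 1L, {
      lapply(seq_len(extra), function(i) {
        s <- t0 + rnorm(length(t0), 0, 0.8)
        # disperse the common-cause prior across starts
        s[which(nms == "p_common")] <-
          log(i / (extra + 1)) - log1p(-i / (extra + 1)) +
          rnorm(1, 0, 0.25)
        s
      })
    })
    starts <- c(starts, jit)
  }

  runs <- lapply(starts, function(s) {
    optim(s, objective, method = "Nelder-Mead",
          control = list(maxit = config$maxit, reltol = config$reltol))
  })
  vals <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(vals))) {
    stop("all optimizer starts failed; per-start values: ",
         paste(signif(vals, 4), collapse = ", "))
  }
  best <- runs[[which.min(vals)]]
  p <- to_box(best$par, config$bounds, nms)
  structure(
    list(strategy = strategy,
         params = params_from_vector(p, free_criterion),
         loglik = -best$value,
         n_responses = prep$n_responses, n_clipped = prep$n_clipped,
         free_criterion = free_criterion, n_par = length(nms),
         diagnostics = list(start_values = -vals,
                            convergence = vapply(runs, function(r)
                              r$convergence, integer(1)),
                            evals = vapply(runs, function(r)
                              r$counts[["function"]], numeric(1))),
         config = config),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: strategy %s, logLik %.2f (%d responses, %d par)\n",
              x$strategy, x$loglik, x$n_responses, x$n_par))
  print(x$params)
  invisible(x)
}

#' Fit all candidate strategies to one subject
#'
#' @inheritParams fit_strategy
#' @param candidate_strategies Strategies to fit (default all three).
#' @param biased_selection Also fit the biased-criterion selection variant
#'   as a fourth candidate (default `FALSE`).
#' @return Named list of [fit_strategy()] results.
#' @export
fit_subject <- function(data, config = fit_config(),
                        candidate_strategies = strategies(),
                        biased_selection = FALSE) {
  fits <- lapply(candidate_strategies, function(s)
    fit_strategy(data, s, config))
  names(fits) <- candidate_strategies
  if (biased_selection) {
    fits$biased_selection <-
      fit_strategy(data, "selection", config, free_criterion = TRUE)
  }
  fits
}

# --- goodness of fit -------------------------------------------------------

#' Log-likelihood of the strategy-free null model
#'
#' The null predicts responses from a single Gaussian per condition type and
#' modality (auditory-only, visual-only, bisensory-auditory,
#' bisensory-visual), fitted to the pooled responses of that type, and
#' evaluated on the same binned grid (with the same probability floor) as
#' the model likelihood, so the two log-likelihoods are commensurable.
#'
#' @param data Subject dataset.
#' @param config A [fit_config()].
#' @return Log-likelihood of the null model.
#' @export
null_loglik <- function(data, config = fit_config()) {
  prep <- prepare_observations(data, config)
  grid <- prep$grid
  groups <- list(
    list(sel = data$cond_type == "A", col = "resp_A"),
    list(sel = data$cond_type == "V", col = "resp_V"),
    list(sel = data$cond_type == "AV", col = "resp_A"),
    list(sel = data$cond_type == "AV", col = "resp_V"))
  ll <- 0
  for (g in groups) {
    r <- data[[g$col]][g$sel]
    r <- r[!is.na(r)]
    if (length(r) == 0) next
    mu <- mean(r); s <- max(sd(r), 0.3)
    p <- pnorm(grid$breaks[-1], mu, s) -
      pnorm(grid$breaks[-length(grid$breaks)], mu, s)
    p <- pmax(p, config$prob_floor)
    p <- p / sum(p)
    ll <- ll + sum(log(p[bin_index(r, grid)]))
  }
  ll
}

#' Nagelkerke generalized coefficient of determination
#'
#' `R2 = (1 - exp(-(2/n) (L1 - L0))) / (1 - exp((2/n) L0))`, where `L1` is
#' the fitted model's log-likelihood, `L0` the null model's, and `n` the
#' number of responses. Bounded above by 1; 0 when the fit does not improve
#' on the null; negative (flagged with a warning) if the fit is worse.
#'
#' @param fit A [fit_strategy()] result (or any list with `loglik` and
#'   `n_responses`).
#' @param L0 Null-model log-likelihood on the same responses, e.g. from
#'   [null_loglik()].
#' @return The generalized R-squared.
#' @export
nagelkerke_r2 <- function(fit, L0) {
  L1 <- fit$loglik
  n <- fit$n_responses
  r2 <- (1 - exp(-(2 / n) * (L1 - L0))) / (1 - exp((2 / n) * L0))
  if (is.finite(r2) && r2 < 0) warning("fit worse than null (negative R^2)")
  r2
}
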
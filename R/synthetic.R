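#' Specification of one synthetic observer
#'
#' Provenance record for recovery studies: which strategy and parameters
#' generate the observer's responses, under which seed.
#'
#' @param strategy Generating strategy, one of [strategies()].
#' @param params Generating [model_params()].
#' @param seed Integer RNG seed for the observer's sensations and uniform
#'   draws.
#' @param subject Subject identifier (string or integer).
#' @return A list of class `"synthetic_subject_spec"`.
#' @export
synthetic_subject_spec <- function(strategy, params = mean_subject_params(),
                                   seed = 1, subject = "S1") {
  strategy <- match_strategy(strategy)
  validate_params(params)
  structure(list(subject = as.character(subject), strategy = strategy,
                 params = params, seed = as.integer(seed)),
            class = "synthetic_subject_spec")
}

#' Generate one synthetic observer's dataset
#'
#' Runs the generative model trial by trial over a design: samples noisy
#' sensations, applies the generating strategy (with a fresh uniform draw
#' per trial for matching), and emits continuous location reports quantized
#' to the 0.1-degree response resolution of the apparatus.
#'
#' @param spec A [synthetic_subject_spec()].
#' @param design An [build_design()] trial list.
#' @return A `subject_data` data frame with columns `subject`, `trial`,
#'   `cond_type`, `s_A`, `s_V`, `resp_A`, `resp_V` (degrees, 1 decimal) and
#'   attribute `spec`.
#' @export
generate_subject <- function(spec, design = build_design()) {
  stopifnot(inherits(spec, "synthetic_subject_spec"))
  n <- nrow(design)
  sim <- with_seed(spec$seed, {
    simulate_trial_responses(as.data.frame(design), spec$params,
                             spec$strategy,
                             z_A = rnorm(n), z_V = rnorm(n), xi = runif(n))
  })
  out <- data.frame(subject = spec$subject, trial = sim$trial,
                    cond_type = sim$cond_type, s_A = sim$s_A, s_V = sim$s_V,
                    resp_A = round(sim$resp_A, 1),
                    resp_V = round(sim$resp_V, 1))
  structure(out, class = c("subject_data", "data.frame"), spec = spec)
}

#' Default between-subject parameter sampler
#'
#' Independent log-normal jitter (25% geometric SD) around the mean-subject
#' values for the three noise/prior SDs, and logit-scale jitter (SD 0.5) for
#' the prior probability of a common cause. Positive support and realistic
#' heterogeneity; medians sit at the mean-subject values.
#'
#' @param center Central [model_params()] (default [mean_subject_params()]).
#' @param sd_log Log-scale SD for the sigmas (default `log(1.25)`).
#' @param sd_logit Logit-scale SD for `p_common` (default 0.5).
#' @return A function `(n)` returning a list of `n` [model_params()].
#' @export
default_param_sampler <- function(center = mean_subject_params(),
                                  sd_log = log(1.25), sd_logit = 0.5) {
  force(center)
  function(n) {
    lapply(seq_len(n), function(i) {
      logit_pc <- log(center$p_common) - log1p(-center$p_common) +
        rnorm(1, 0, sd_logit)
      model_params(
        sigma_A = center$sigma_A * exp(rnorm(1, 0, sd_log)),
        sigma_V = center$sigma_V * exp(rnorm(1, 0, sd_log)),
        sigma_P = center$sigma_P * exp(rnorm(1, 0, sd_log)),
        p_common = plogis_(logit_pc),
        criterion = center$criterion)
    })
  }
}

#' Generate a cohort of synthetic observers
#'
#' `n_per_strategy` observers are generated for each requested strategy,
#' with per-subject parameters drawn from `param_sampler` (or held fixed at
#' `params` when `param_sampler` is `NULL`). Full provenance (spec per
#' subject) travels with the result.
#'
#' @param n_per_strategy Observers per strategy; either a single count or a
#'   named vector over [strategies()] (zero allowed).
#' @param param_sampler `NULL` for fixed parameters, or a function `(n)`
#'   returning a list of [model_params()], e.g. [default_param_sampler()].
#' @param params Fixed generating parameters when `param_sampler` is `NULL`.
#' @param seed Master integer seed; per-subject seeds and sampler draws
#'   derive from it.
#' @param design Trial list shared by all observers.
#' @return A list of class `"cohort"`: `subjects` (list of `subject_data`),
#'   `specs`, `design`, `seed`.
#' @export
generate_cohort <- function(n_per_strategy, param_sampler = NULL,
                            params = mean_subject_params(), seed = 1,
                            design = build_design(seed = seed)) {
  if (is.null(names(n_per_strategy))) {
    n_per_strategy <- setNames(rep(n_per_strategy, 3), strategies())
  }
  stopifnot(all(names(n_per_strategy) %in% strategies()))
  total <- sum(n_per_strategy)
  draws <- with_seed(seed, {
    list(param_list = if (is.null(param_sampler)) {
           rep(list(params), total)
         } else param_sampler(total),
         subj_seeds = sample.int(.Machine$integer.max - 1L, total))
  })
  specs <- vector("list", total)
  k <- 0L
  for (strat in names(n_per_strategy)) {
    for (i in seq_len(n_per_strategy[[strat]])) {
      k <- k + 1L
      specs[[k]] <- synthetic_subject_spec(
        strategy = strat, params = draws$param_list[[k]],
        seed = draws$subj_seeds[[k]],
        subject = sprintf("%s_%02d", strat, i))
    }
  }
  subjects <- lapply(specs, generate_subject, design = design)
  structure(list(subjects = subjects, specs = specs, design = design,
                 seed = seed),
            class = "cohort")
}
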
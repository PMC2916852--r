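# Shared fixtures: small configurations keep the routine tests fast; the
# full-scale recovery study lives in test-acceptance.R.

msp <- mean_subject_params()

quick_config <- function(...) {
  fit_config(mc_samples = 1500, restarts = 3, maxit = 120, seed = 42, ...)
}

small_subject <- function(strategy = "matching", seed = 7,
                          params = mean_subject_params(),
                          design = build_design(repetitions = 15,
                                                seed = seed)) {
  generate_subject(
    synthetic_subject_spec(strategy, params, seed = seed,
                           subject = paste0(strategy, "_t", seed)),
    design)
}

# hand-built structure_estimates with a pinned causal posterior
fake_estimates <- function(post_c1, fused = -5, seg_A = 10, seg_V = -12) {
  structure(list(s_hat_A_c1 = rep(fused, length(post_c1)),
                 s_hat_V_c1 = rep(fused, length(post_c1)),
                 s_hat_A_c2 = rep(seg_A, length(post_c1)),
                 s_hat_V_c2 = rep(seg_V, length(post_c1)),
                 post_c1 = post_c1),
            class = "structure_estimates")
}

fake_fit <- function(strategy, loglik, n_par = 4, n_responses = 900) {
  structure(list(strategy = strategy, loglik = loglik, n_par = n_par,
                 n_responses = n_responses),
            class = "fit_result")
}
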
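# causalstrat

Which decision rule does an observer use when localizing a sound that may —
or may not — share a source with a flash? `causalstrat` implements the
Bayesian causal-inference model of auditory-visual spatial localization
together with three decision strategies for turning the causal-structure
posterior into a location report, and the machinery to decide, from an
individual observer's trial-by-trial data, which strategy they used. It is
aimed at psychophysicists modeling multisensory localization data and at
anyone who wants a worked, testable reference implementation of
causal-inference strategy classification.

## The model

On each bisensory trial the observer receives noisy sensations
`x_A ~ N(s_A, σ_A²)` and `x_V ~ N(s_V, σ_V²)` of the true azimuths, with a
central Gaussian prior `N(0, σ_P²)` over source locations. Bayes' rule
gives the posterior probability `π = p(C = 1 | x_A, x_V)` that the two
sensations share a common cause, given the prior probability `p_common`.
Conditional on the structure, the location estimates are precision-weighted
means: fused (`C = 1`) or independently shrunk toward straight ahead
(`C = 2`). The three strategies map `(π, ŝ_C=1, ŝ_C=2)` to the reported
location:

* **model averaging** — report `π·ŝ_C=1 + (1−π)·ŝ_C=2` (minimizes expected
  squared error);
* **model selection** — report the estimate of the more probable structure
  (`π` vs a 0.5 criterion; optionally a free criterion);
* **probability matching** — choose the common-cause structure with
  probability `π`, via a fresh uniform draw each trial.

Each strategy has four free parameters (`σ_A`, `σ_V`, `σ_P`, `p_common`).
Per-subject fitting maximizes a simulation-based likelihood (Monte-Carlo
response histograms per condition, 1° bins), and subjects are classified by
the strategy with the highest log-likelihood, gated by a log-likelihood
margin over the runner-up (3 by default), with BIC available for the
five-parameter biased-selection variant.

## Worked example

Generate a synthetic probability-matching observer on the standard design
(5 azimuths, 35 conditions, 525 trials), fit all three strategies, and
classify:

```r
library(causalstrat)

dat <- generate_subject(
  synthetic_subject_spec("matching", mean_subject_params(), seed = 11),
  build_design(repetitions = 15, seed = 3))

cfg  <- fit_config(mc_samples = 2000, restarts = 4, maxit = 150, seed = 7)
fits <- fit_subject(dat, cfg)
cl   <- classify_subject(fits, margin_threshold = 3, subject = "demo")

round(cl$logliks, 1)
#> averaging selection  matching
#>   -2614.2   -2581.8   -2562.7
cl$winner
#> [1] "matching"
round(cl$margin, 1)
#> [1] 19.1
round(nagelkerke_r2(fits$matching, null_loglik(dat, cfg)), 2)
#> [1] 0.84
print(fits$matching$params)
#> causal-inference model parameters:
#>   sigma_A = 11.2 deg, sigma_V = 2.64 deg, sigma_P = 28.8 deg
#>   p_common = 0.577, selection criterion = 0.5
```

The observer was generated with `σ_A = 10.1°, σ_V = 2.5°, σ_P = 33°,
p_common = 0.57`; the matching fit recovers those values, wins by a
log-likelihood margin of 19.1 (well past the inclusion threshold of 3), and
explains ~84% of the response variance in the Nagelkerke sense. The
simulated response distributions show the strategy signatures directly:

```r
d_avg <- simulate_condition(list(s_A = 13, s_V = -13), mean_subject_params(),
                            "averaging", n = 10000, seed = 2)
d_sel <- simulate_condition(list(s_A = 13, s_V = -13), mean_subject_params(),
                            "selection", n = 10000, seed = 2)
as.integer(bimodality_diagnostic(d_avg))  # 1  (unimodal)
as.integer(bimodality_diagnostic(d_sel))  # 2  (bimodal: capture + segregation)
```

Cohort-level validation (generate → fit → classify → tabulate) is one
call: `run_recovery(generate_cohort(n_per_strategy = 20, seed = 1))`.

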
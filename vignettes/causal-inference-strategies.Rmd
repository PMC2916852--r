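---
title: "Decision strategies in audiovisual causal inference: model, fitting, and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision strategies in audiovisual causal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalstrat)
```

## The problem

When a brief sound and a brief flash occur at nearby azimuths, an observer
must implicitly decide whether they came from one object or two before
localizing either. `causalstrat` implements the Bayesian causal-inference
model of this task and, on top of it, three *decision strategies* that turn
the inferred causal structure into an overt location report. The package's
purpose is to ask, for a single observer's trial-by-trial localization data,
which strategy explains their behavior best — and to validate, on synthetic
observers whose strategy is known by construction, that the fitting and
classification machinery can actually make that call.

## Generative model

On a bisensory trial with true source azimuths $s_A$ (auditory) and $s_V$
(visual), the observer receives noisy sensations

$$x_A \sim \mathcal{N}(s_A, \sigma_A^2), \qquad
  x_V \sim \mathcal{N}(s_V, \sigma_V^2),$$

independent across trials and channels. A Gaussian spatial prior
$\mathcal{N}(0, \sigma_P^2)$ encodes the central bias toward straight ahead;
its mean is fixed at 0° and is not a free parameter. The observer entertains
two causal structures: a common cause ($C=1$, one source generated both
sensations) and independent causes ($C=2$). With prior probability
$p_\mathrm{common} = p(C=1)$, Bayes' rule gives

$$p(C=1 \mid x_A, x_V) =
  \frac{p(x_A, x_V \mid C=1)\, p_\mathrm{common}}
       {p(x_A, x_V \mid C=1)\, p_\mathrm{common} +
        p(x_A, x_V \mid C=2)\,(1 - p_\mathrm{common})}.$$

Both likelihoods have closed forms: under $C=1$ the shared source is
marginalized over the prior (a single Gaussian integral), and under $C=2$
the density factorizes into per-modality marginals
$\mathcal{N}(x; 0, \sigma^2 + \sigma_P^2)$. `likelihood_c1()` and
`likelihood_c2()` evaluate these in log space so large audiovisual
discrepancies cannot underflow, and the test suite pins both to numerical
quadrature at $10^{-8}$ relative tolerance.

The per-structure location estimates are the usual precision-weighted
means: under $C=1$ both modalities share the fused estimate

$$\hat{s}_{C=1} = \frac{x_A/\sigma_A^2 + x_V/\sigma_V^2}
  {1/\sigma_A^2 + 1/\sigma_V^2 + 1/\sigma_P^2},$$

and under $C=2$ each sensation is shrunk toward the prior on its own,
$\hat{s}_{C=2} = x\,\sigma_P^2 / (\sigma_P^2 + \sigma^2)$. Unisensory
trials use the same single-cue shrinkage; no causal inference is invoked
there. (Whether observers apply prior shrinkage on unisensory trials cannot
be distinguished from a slightly different $\sigma$ in this design; we use
shrinkage for internal consistency.)

## The three strategies

Writing $\pi = p(C=1 \mid x_A, x_V)$:

* **Model averaging** reports
  $\pi\,\hat{s}_{C=1} + (1-\pi)\,\hat{s}_{C=2}$ — the posterior-mean
  estimate, optimal under squared-error loss. Response distributions are
  mostly unimodal.
* **Model selection** reports the estimate of whichever structure is more
  probable ($\pi$ vs a fixed criterion of 0.5). Responses are bimodal at
  moderate conflicts, with cleanly separated modes.
* **Probability matching** draws $\xi \sim \mathrm{Uniform}(0,1)$ afresh
  each trial and reports the common-cause estimate iff $\pi > \xi$, so each
  structure is chosen with probability equal to its posterior. Responses
  are bimodal with overlapping, graded mode weights.

Two conventions are fixed for reproducibility. First, ties
($\pi$ exactly equal to the threshold) resolve to the independent-cause
structure; the event has probability zero under the continuous model but
must be deterministic in code. Second, the inequality direction for
matching ($C=1$ iff $\pi > \xi$ rather than $\pi > 1-\xi$) is a labeling
choice with identical behavior; the package documents and uses the former.
Third, on a bisensory trial a *single* structure choice governs both the
auditory and the visual report for selection and matching: the trial's
causal interpretation is one inference, reported twice. A biased-selection
variant frees the criterion as a fifth parameter in $[0,1]$.

## Forward simulation

`simulate_condition()` draws `n` trials of one condition, pushes them
through a strategy, and bins the continuous reports at 0.1° over ±67°
(half the 134°-wide response screen, matching the 0.1°/pixel response
resolution). No motor noise is added: response variability comes entirely
from sensory noise and, for matching, the structure draw. This is a
deliberate modeling assumption, not an omission — adding a motor kernel
would blur the bimodality signature that identifies the strategies.

`bimodality_diagnostic()` smooths a binned distribution with a fixed 1.5°
Gaussian kernel (the visual stimulus envelope scale) and counts local
maxima by *topographic prominence*: a peak counts only if it rises at least
10% of the global maximum above the valley separating it from a taller
peak. Plain local-maximum counting misreads Monte-Carlo ripple on the broad
plateaus that model averaging produces at large conflicts; prominence-based
counting classifies averaging as unimodal and selection/matching as bimodal
across the standard conditions, which is exactly the qualitative signature
the strategies predict.

## Synthetic observers

`build_design()` reproduces the session structure: 5 auditory-only and 5
visual-only conditions plus the full 5×5 bisensory cross of the azimuths
{−13°, −6.5°, 0°, 6.5°, 13°}, each repeated 15 times in a seeded
pseudorandom order — 525 trials. `generate_subject()` runs the generative
process with a known strategy and parameters and quantizes reports to 0.1°.
The default generating parameters are the mean-subject values
$\sigma_V = 2.5°$, $\sigma_A = 10.1°$, $\sigma_P = 33.0°$,
$p_\mathrm{common} = 0.57$ (`mean_subject_params()`).

For heterogeneous cohorts, `default_param_sampler()` jitters the three SDs
log-normally (25% geometric SD) and $p_\mathrm{common}$ on the logit scale
(SD 0.5) around the mean-subject values. Only the across-subject *means* of
fitted parameters are established for this task; the spread is a modeling
choice, chosen to resemble plausible between-subject variability while
keeping every draw in the psychophysically reasonable range, and it is
fully exposed as an argument. Synthetic data emulate the design, the
response resolution, and the generative response process; they do not
emulate lapses, response-order effects, motor noise, eccentricity-dependent
noise, or learning across the session, so recovery results bound what the
pipeline can do on well-behaved data rather than guaranteeing performance
on any human dataset.

## Fitting

Human reports are continuous, and the model's response distribution under
selection/matching has no closed form, so the likelihood is built by
simulation (`response_loglik()`): for each condition, `mc_samples` forward
draws are binned in 1° bins over ±67°, each bin probability is floored at
$10^{-6}$ and the histogram renormalized, and the observed responses (both
reports on bisensory trials — 900 responses for a standard session) are
scored by their bin's log-probability. The floor keeps a response in an
unvisited bin finite rather than vetoing a parameter set outright; both the
bin width and the floor are `fit_config()` arguments, since a kernel
density or a different bin width are defensible alternatives.

Two numerical choices matter:

* **Common random numbers.** The same standard-normal and uniform draws are
  reused for every likelihood evaluation inside one fit, making the
  objective a deterministic function of the parameters. Without this, the
  optimizer chases Monte-Carlo noise.
* **Bounded multi-start Nelder-Mead.** The binned MC objective is
  piecewise-constant at a fine scale, so derivative-free simplex search on
  logistic-transformed coordinates (boxes: $\sigma_A, \sigma_V \in [0.1,
  45]$, $\sigma_P \in [1, 200]$, $p_\mathrm{common}, \text{criterion} \in
  [0, 1]$ — generous psychophysical ranges) is used. The first start is
  moment-based: unisensory response SDs estimate the sensory noises, and
  the regression slope of mean auditory response on true location
  estimates the prior shrinkage $\sigma_P^2/(\sigma_P^2+\sigma_A^2)$,
  hence $\sigma_P$. Remaining starts jitter this point and disperse
  $p_\mathrm{common}$ across its range, which is the coordinate most prone
  to local optima. The inner loop (response generation, binning, scoring)
  is compiled C++ mirroring the exported R reference functions; a test
  asserts bin-exact agreement between the two paths.

Goodness of fit is Nagelkerke's generalized $R^2$ against a strategy-free
null that predicts each response from one Gaussian per condition type and
modality, evaluated on the same binned grid so the two likelihoods are
commensurable. The null model is not standardized in this literature; ours
is deliberately simple and is exposed through `null_loglik()` so a
different baseline can be substituted.

## Classification

`classify_subject()` ranks the per-strategy log-likelihoods; the winner's
margin over the runner-up (natural-log units) gates inclusion, with 3
("substantial evidence" on the Jeffreys reading) the default and 10 a
sensitivity setting. Whether such margins were historically quoted in
natural-log or log10 units is ambiguous; the package treats the threshold
as natural-log and leaves it as an argument. `bic()` adds the
$k\ln n$ complexity penalty used when the biased-selection variant (5
parameters) competes against the 4-parameter models; with equal parameter
counts BIC ordering coincides with likelihood ordering, so the variant only
matters in the dedicated four-model analysis mode. `tabulate_cohort()`
reports counts and percentages under no exclusion and under margins 3 and
10, mirroring the robustness checks customary for this analysis.

## Problem sizes and runtime choices

The package-level validation study (`run_recovery()` in the acceptance
tests) uses 20 synthetic observers per strategy at the mean-subject
parameters, the full 525-trial design, 2,000 MC samples per condition
during fitting, and 4 optimizer starts with at most 150 simplex iterations
each. These sizes make the full study run in minutes on a laptop core while
leaving classification accuracy and parameter recovery comfortably
measurable; `fit_config()` defaults are larger (10,000 samples, 20 starts)
and are what we would recommend for fitting real observers, where compute
is spent once rather than 180 times.

## Known limitations

* The likelihood is simulation-based; at very small `mc_samples` the
  probability floor dominates sparse bins and margins between strategies
  compress. At 10,000 samples per condition, doubling `mc_samples` moves a
  525-trial log-likelihood by a few units at most — a fraction of a
  percent of its magnitude and an order of magnitude below typical
  between-strategy margins; the test suite checks this relative
  stability. Read margins smaller than a few units as MC-indistinguishable.
* Selection and matching predict responses on the *same* support; they
  differ only in mode weights. At small audiovisual conflicts (where the
  posterior rarely approaches the criterion) the two strategies are
  genuinely hard to separate, and margins near the exclusion threshold
  should be read as "not decisively classified", not as evidence of a
  mixed strategy.
* The model assumes stationary, eccentricity-independent Gaussian noise
  and a fixed prior across the session. Real observers drift.
* `p_common` trades off against $\sigma_P$ in shaping interaction
  strength; with 525 trials the recovery study shows both are
  identifiable, but expect wider uncertainty on $\sigma_P$ than on the
  sensory noises.
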
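# Simulation-based likelihood, optimizer, and goodness of fit.

test_that("the response likelihood is finite, seeded, and order-invariant", {
  dat <- small_subject("averaging", seed = 21)
  cfg <- quick_config()
  ll <- response_loglik(dat, msp, "averaging", config = cfg)
  expect_true(is.finite(ll))
  expect_equal(attr(ll, "n_responses"), 900)  # 150 unisensory + 2 x 375
  expect_equal(attr(ll, "n_clipped"), 0)
  # same seed => identical value
  expect_equal(as.numeric(response_loglik(dat, msp, "averaging",
                                          config = cfg)),
               as.numeric(ll))
  # the likelihood is a sum over trials: permuting them changes nothing
  perm <- dat[sample(nrow(dat)), ]
  expect_equal(as.numeric(response_loglik(perm, msp, "averaging",
                                          config = cfg)),
               as.numeric(ll))
})

test_that("single-response likelihood equals the binned MC probability", {
  # one auditory-only trial; the predicted histogram is rebuilt through the
  # R reference path with the same common random numbers
  dat <- data.frame(subject = "s", trial = 1, cond_type = "A",
                    s_A = 6.5, s_V = NA_real_, resp_A = 4.2,
                    resp_V = NA_real_)
  cfg <- fit_config(mc_samples = 2000, seed = 13)
  ll <- response_loglik(dat, msp, "averaging", config = cfg)

  crn <- causalstrat:::draw_crn(1, 2000, 13)
  x <- 6.5 + msp$sigma_A * crn$z_A
  r <- estimate_c2(x, msp$sigma_A, msp)
  grid <- response_grid(67, 1)
  p <- tabulate(causalstrat:::bin_index(r, grid),
                length(grid$centers)) / 2000
  p <- pmax(p, cfg$prob_floor)
  psum <- sum(p)
  expect_equal(as.numeric(ll),
               log(p[causalstrat:::bin_index(4.2, grid)] / psum),
               tolerance = 1e-12)

  # a response in a region of zero predicted mass hits the floor, not -Inf
  dat$resp_A <- -60
  ll0 <- response_loglik(dat, msp, "averaging", config = cfg)
  expect_true(is.finite(ll0))
  expect_equal(as.numeric(ll0),
               log(cfg$prob_floor / psum),
               tolerance = 1e-10)
})

test_that("responses outside the grid are clipped with a warning", {
  dat <- data.frame(subject = "s", trial = 1:2, cond_type = "A",
                    s_A = 0, s_V = NA_real_, resp_A = c(3, 80),
                    resp_V = NA_real_)
  expect_warning(ll <- response_loglik(dat, msp, "averaging",
                                       config = quick_config()),
                 "clipped")
  expect_equal(attr(ll, "n_clipped"), 1)
})

test_that("dataset validation rejects malformed inputs", {
  cfg <- quick_config()
  expect_error(response_loglik(data.frame(), msp, "matching", config = cfg))
  bad <- small_subject("matching", seed = 2)
  bad$resp_V[bad$cond_type == "AV"][1] <- NA
  expect_error(response_loglik(bad, msp, "matching", config = cfg),
               "bisensory")
})

test_that("the generating parameters beat distant parameters", {
  far <- model_params(sigma_A = 25, sigma_V = 10, sigma_P = 8,
                      p_common = 0.05)
  wins <- 0
  for (seed in 1:10) {
    dat <- small_subject("matching", seed = 400 + seed)
    cfg <- fit_config(mc_samples = 1500, seed = 500 + seed)
    l_true <- response_loglik(dat, msp, "matching", config = cfg)
    l_far <- response_loglik(dat, far, "matching", config = cfg)
    wins <- wins + (l_true > l_far)
  }
  expect_gte(wins, 10 * 0.95)
})

test_that("the likelihood surface peaks near the generating parameters", {
  # +50% single-coordinate perturbations should lose in the clear majority
  # of replicates
  total <- wins <- 0
  for (seed in 1:5) {
    dat <- small_subject("averaging", seed = 600 + seed)
    cfg <- fit_config(mc_samples = 1500, seed = 700 + seed)
    l_true <- response_loglik(dat, msp, "averaging", config = cfg)
    for (coord in c("sigma_A", "sigma_V", "sigma_P")) {
      p <- unclass(msp)
      p[[coord]] <- p[[coord]] * 1.5
      pert <- do.call(model_params, p)
      total <- total + 1
      wins <- wins + (l_true > response_loglik(dat, pert, "averaging",
                                               config = cfg))
    }
  }
  expect_gt(wins / total, 0.5)
})

test_that("fitting recovers plausible parameters on one observer", {
  dat <- small_subject("averaging", seed = 31)
  fit <- fit_strategy(dat, "averaging", quick_config())
  expect_s3_class(fit, "fit_result")
  expect_true(is.finite(fit$loglik))
  expect_equal(fit$n_par, 4)
  expect_lt(abs(fit$params$sigma_V / 2.5 - 1), 0.3)
  expect_length(fit$diagnostics$start_values, quick_config()$restarts)
  # the optimum cannot be worse than the generating parameters
  l_true <- response_loglik(dat, msp, "averaging",
                            config = quick_config())
  expect_gte(fit$loglik, as.numeric(l_true) - 1e-9)
})

test_that("the biased-selection variant adds one free parameter", {
  dat <- small_subject("selection", seed = 41)
  cfg <- fit_config(mc_samples = 800, restarts = 2, maxit = 60, seed = 4)
  fit <- fit_strategy(dat, "selection", cfg, free_criterion = TRUE)
  expect_equal(fit$n_par, 5)
  expect_true(fit$params$criterion >= 0 && fit$params$criterion <= 1)
})

test_that("the MC likelihood is stable under more simulation samples", {
  # doubling the per-condition sample count moves the log-likelihood by a
  # small fraction of its magnitude (and far less than typical
  # between-strategy margins)
  for (seed in 1:2) {
    dat <- small_subject("matching", seed = 100 + seed)
    l1 <- response_loglik(dat, msp, "matching",
                          config = fit_config(mc_samples = 10000,
                                              seed = 50 + seed))
    l2 <- response_loglik(dat, msp, "matching",
                          config = fit_config(mc_samples = 20000,
                                              seed = 50 + seed))
    expect_lt(abs(l1 - l2) / abs(l1), 0.003)
  }
})

test_that("Nagelkerke R^2 matches its closed form and limits", {
  f <- function(l1) fake_fit("matching", l1, n_responses = 900)
  L0 <- -2000
  expect_equal(nagelkerke_r2(f(-2000), L0), 0)
  l1 <- -1500
  expect_equal(nagelkerke_r2(f(l1), L0),
               (1 - exp(-(2 / 900) * (l1 - L0))) / (1 - exp((2 / 900) * L0)))
  expect_lte(nagelkerke_r2(f(-1), L0), 1)
  # approaches 1 as the per-response likelihood approaches certainty
  expect_gt(nagelkerke_r2(f(-1e-9), L0), 0.999)
  expect_warning(nagelkerke_r2(f(-2100), L0), "negative")
})

test_that("the null model is a fair baseline on real-structure data", {
  dat <- small_subject("matching", seed = 51)
  cfg <- quick_config()
  L0 <- null_loglik(dat, cfg)
  expect_true(is.finite(L0))
  # the generating model at its true parameters outperforms the null
  l1 <- response_loglik(dat, msp, "matching", config = cfg)
  expect_gt(as.numeric(l1), L0)
})
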
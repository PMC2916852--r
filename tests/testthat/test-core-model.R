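# Closed-form generative model: likelihoods, causal posterior, per-structure
# estimates, and the three strategy rules.

# Quadrature over a window that provably contains the mass of a product of
# Gaussians (precision-weighted center, +- 20 posterior SDs); doubly
# infinite limits can miss very narrow products.
quad_gauss_product <- function(f, means, sds) {
  w <- 1 / sds^2
  m <- sum(means * w) / sum(w)
  h <- 1 / sqrt(sum(w))
  integrate(f, m - 20 * h, m + 20 * h, rel.tol = 1e-12,
            subdivisions = 500L)$value
}

quad_lik_c1 <- function(x_A, x_V, p) {
  quad_gauss_product(
    function(s) dnorm(x_A, s, p$sigma_A) * dnorm(x_V, s, p$sigma_V) *
      dnorm(s, 0, p$sigma_P),
    c(x_A, x_V, 0), c(p$sigma_A, p$sigma_V, p$sigma_P))
}

quad_lik_c2 <- function(x_A, x_V, p) {
  ia <- quad_gauss_product(
    function(s) dnorm(x_A, s, p$sigma_A) * dnorm(s, 0, p$sigma_P),
    c(x_A, 0), c(p$sigma_A, p$sigma_P))
  iv <- quad_gauss_product(
    function(s) dnorm(x_V, s, p$sigma_V) * dnorm(s, 0, p$sigma_P),
    c(x_V, 0), c(p$sigma_V, p$sigma_P))
  ia * iv
}

test_that("parameter constructor enforces the domain", {
  expect_error(model_params(-1, 2.5, 33, 0.5), "sigma_A")
  expect_error(model_params(10, 0, 33, 0.5), "sigma_V")
  expect_error(model_params(10, 2.5, 33, 1.2), "p_common")
  expect_error(model_params(10, 2.5, 33, 0.5, criterion = -0.1), "criterion")
  expect_s3_class(mean_subject_params(), "model_params")
})

test_that("closed-form likelihoods match quadrature oracles", {
  unit <- model_params(1, 1, 1, 0.5)
  expect_equal(likelihood_c1(0, 0, unit), 1 / (2 * pi * sqrt(3)),
               tolerance = 1e-12)
  expect_equal(likelihood_c2(0, 0, unit), (1 / sqrt(2 * pi * 2))^2,
               tolerance = 1e-12)

  # the worked bisensory sensation pair at mean-subject parameters
  expect_equal(likelihood_c1(10.1, 2.5, msp), quad_lik_c1(10.1, 2.5, msp),
               tolerance = 1e-8)

  set.seed(11)
  for (i in 1:100) {
    p <- model_params(sigma_A = runif(1, 0.5, 30), sigma_V = runif(1, 0.5, 30),
                      sigma_P = runif(1, 2, 100), p_common = runif(1))
    x_A <- runif(1, -40, 40); x_V <- runif(1, -40, 40)
    expect_equal(likelihood_c1(x_A, x_V, p), quad_lik_c1(x_A, x_V, p),
                 tolerance = 1e-8)
    expect_equal(likelihood_c2(x_A, x_V, p), quad_lik_c2(x_A, x_V, p),
                 tolerance = 1e-8)
  }
})

test_that("common-cause likelihood is symmetric when the noises are equal", {
  p <- model_params(4, 4, 20, 0.5)
  expect_equal(likelihood_c1(7, -2, p), likelihood_c1(-2, 7, p))
})

test_that("independent-cause likelihood factorizes into modality marginals", {
  set.seed(3)
  for (i in 1:10) {
    x_A <- runif(1, -30, 30); x_V <- runif(1, -30, 30)
    expect_equal(
      likelihood_c2(x_A, x_V, msp),
      dnorm(x_A, 0, sqrt(msp$sigma_A^2 + msp$sigma_P^2)) *
        dnorm(x_V, 0, sqrt(msp$sigma_V^2 + msp$sigma_P^2)))
  }
})

test_that("causal posterior behaves like a posterior", {
  p1 <- model_params(10.1, 2.5, 33, 1)
  p0 <- model_params(10.1, 2.5, 33, 0)
  expect_equal(posterior_c1(c(-20, 0, 14), c(3, 3, 3), p1), rep(1, 3))
  expect_equal(posterior_c1(c(-20, 0, 14), c(3, 3, 3), p0), rep(0, 3))

  grid <- expand.grid(x_A = seq(-40, 40, by = 4), x_V = seq(-40, 40, by = 4))
  post <- posterior_c1(grid$x_A, grid$x_V, msp)
  expect_true(all(post >= 0 & post <= 1))

  # decreasing in the audiovisual discrepancy, other things equal
  disc <- seq(0, 50, by = 1)
  post_d <- posterior_c1(disc / 2, -disc / 2, msp)
  expect_true(all(diff(post_d) < 0))

  # where the two likelihoods cross, the posterior reduces to the prior
  p <- model_params(3, 3, 25, 0.37)
  gap <- uniroot(function(d) likelihood_c1(d / 2, -d / 2, p, log = TRUE) -
                   likelihood_c2(d / 2, -d / 2, p, log = TRUE),
                 c(0, 100), tol = 1e-12)$root
  expect_equal(posterior_c1(gap / 2, -gap / 2, p), 0.37, tolerance = 1e-9)
})

test_that("fused estimate is the mean of the normalized Gaussian product", {
  expect_equal(estimate_c1(0, 0, msp), 0)

  sym <- model_params(5, 5, 1e7, 0.5)
  expect_equal(estimate_c1(8, -2, sym), 3, tolerance = 1e-6)

  # posterior over s given C=1 is prop. to N(x_A; s)N(x_V; s)N(s; 0): its
  # mean (= mode) computed numerically must equal the precision-weighted form
  logpost <- function(s, x_A, x_V) {
    dnorm(x_A, s, msp$sigma_A, log = TRUE) +
      dnorm(x_V, s, msp$sigma_V, log = TRUE) +
      dnorm(s, 0, msp$sigma_P, log = TRUE)
  }
  mode_hat <- optimize(logpost, c(-40, 40), x_A = 21, x_V = 1,
                       maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(estimate_c1(21, 1, msp), mode_hat, tolerance = 1e-6)

  num <- quad_gauss_product(function(s) s * exp(logpost(s, 21, 1)),
                            c(21, 1, 0),
                            c(msp$sigma_A, msp$sigma_V, msp$sigma_P))
  den <- quad_gauss_product(function(s) exp(logpost(s, 21, 1)),
                            c(21, 1, 0),
                            c(msp$sigma_A, msp$sigma_V, msp$sigma_P))
  expect_equal(estimate_c1(21, 1, msp), num / den, tolerance = 1e-8)

  # lies between the data and the prior mean
  est <- estimate_c1(21, 1, msp)
  expect_gt(est, 0); expect_lt(est, 21)
  expect_error(estimate_c1(NA, 3, msp), "both sensations")
})

test_that("single-cue estimate shrinks toward straight ahead", {
  expect_equal(estimate_c2(0, msp$sigma_A, msp), 0)
  expect_equal(estimate_c2(13, 10.1, msp), 13 * 33^2 / (33^2 + 10.1^2))
  flat <- model_params(10.1, 2.5, 1e8, 0.5)
  expect_equal(estimate_c2(13, 10.1, flat), 13, tolerance = 1e-6)
  x <- c(-20, -3, 5, 30)
  s <- estimate_c2(x, msp$sigma_A, msp)
  expect_true(all(abs(s) <= abs(x)))
  expect_true(all(sign(s) == sign(x)))
})

test_that("strategy rules map the posterior to final estimates", {
  expect_error(apply_strategy("bogus", fake_estimates(0.5), msp), "arg")

  # certainty of a common cause: all strategies fuse
  e1 <- fake_estimates(1)
  for (s in strategies()) {
    out <- apply_strategy(s, e1, msp, xi = 0.5)
    expect_equal(out$s_hat_A, e1$s_hat_A_c1)
    expect_equal(out$s_hat_V, e1$s_hat_V_c1)
  }

  # averaging at posterior 0.5: midpoint of the two structures
  mid <- apply_strategy("averaging", fake_estimates(0.5), msp)
  expect_equal(mid$s_hat_A, (-5 + 10) / 2)
  expect_equal(mid$s_hat_V, (-5 - 12) / 2)

  # averaging is a convex combination for any posterior
  post <- runif(50)
  avg <- apply_strategy("averaging", fake_estimates(post), msp)
  expect_true(all(avg$s_hat_A >= pmin(-5, 10) & avg$s_hat_A <= pmax(-5, 10)))

  # selection at posterior 0.30 picks the independent structure, and one
  # structure choice governs both modality reports
  sel <- apply_strategy("selection", fake_estimates(0.3), msp)
  expect_equal(sel$s_hat_A, 10)
  expect_equal(sel$s_hat_V, -12)

  # tie at the criterion resolves to independent causes
  tie <- apply_strategy("selection", fake_estimates(0.5), msp)
  expect_equal(tie$s_hat_A, 10)

  # matching with a degenerate point-mass draw at 0.5 reduces to selection
  post <- runif(200)
  m <- apply_strategy("matching", fake_estimates(post), msp, xi = 0.5)
  s <- apply_strategy("selection", fake_estimates(post), msp)
  expect_equal(m$s_hat_A, s$s_hat_A)
  expect_equal(m$s_hat_V, s$s_hat_V)
  expect_error(apply_strategy("matching", fake_estimates(0.5), msp),
               "uniform draw")
})

test_that("matching chooses the common structure at its posterior rate", {
  set.seed(19)
  for (post in c(0.15, 0.5, 0.85)) {
    n <- 10000
    out <- apply_strategy("matching", fake_estimates(rep(post, n)), msp,
                          xi = runif(n))
    freq <- mean(out$s_hat_A == -5)
    ci_half <- 2.576 * sqrt(post * (1 - post) / n)
    expect_lt(abs(freq - post), ci_half + 1e-12)
  }
})
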
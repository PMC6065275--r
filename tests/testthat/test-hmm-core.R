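test_that("emission log-density matches closed forms and a quadratic-form oracle", {
  p <- hmm_parameters(0.9, 0.9, mu = matrix(c(2, 2, 4, 4), 2, byrow = TRUE),
                      sigma = matrix(1, 2, 2), rho = c(0, 0))
  # at the mean with identity covariance: -log(2*pi)
  expect_equal(emission_logdensity(c(2, 2), "R", p), -log(2 * pi))

  # rho = 0 factorises into two univariate normals
  p2 <- hmm_parameters(0.9, 0.9, mu = matrix(c(1, 2, 4, 5), 2, byrow = TRUE),
                       sigma = matrix(c(0.5, 1.2, 0.8, 2), 2, byrow = TRUE),
                       rho = c(0, 0))
  x <- c(1.7, 0.4)
  expect_equal(emission_logdensity(x, "M", p2),
               dnorm(x[1], 4, 0.8, log = TRUE) + dnorm(x[2], 5, 2, log = TRUE))

  # random cases against an explicit 2x2 inverse/determinant oracle
  set.seed(21)
  for (i in 1:20) {
    p3 <- random_params()
    x <- rnorm(2, 3, 2)
    for (s in c("R", "M")) {
      S <- diag(p3$sigma[s, ]) %*%
        matrix(c(1, p3$rho[[s]], p3$rho[[s]], 1), 2) %*% diag(p3$sigma[s, ])
      z <- x - p3$mu[s, ]
      detS <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
      Sinv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / detS
      oracle <- -log(2 * pi) - 0.5 * log(detS) -
        0.5 * drop(t(z) %*% Sinv %*% z)
      expect_equal(emission_logdensity(x, s, p3), oracle, tolerance = 1e-10)
    }
  }
})

test_that("forward log-likelihood has its closed forms at the edges", {
  p <- random_params()
  set.seed(2)
  x <- list(h = rnorm(1, 3), v = rnorm(1, 3))
  # T = 1: mixture over the uniform initial distribution
  expect_equal(forward_loglik(x, p),
               log(0.5 * exp(emission_logdensity(c(x$h, x$v), "R", p)) +
                   0.5 * exp(emission_logdensity(c(x$h, x$v), "M", p))),
               tolerance = 1e-10)

  # identical emissions in both states: iid log-likelihood, Gamma-free
  mu <- matrix(c(3, 3, 3, 3), 2, byrow = TRUE)
  sg <- matrix(0.7, 2, 2)
  pid1 <- hmm_parameters(0.99, 0.99, mu, sg, c(0.2, 0.2))
  pid2 <- hmm_parameters(0.30, 0.70, mu, sg, c(0.2, 0.2))
  set.seed(3)
  y <- list(h = rnorm(30, 3, 0.7), v = rnorm(30, 3, 0.7))
  iid <- sum(emission_logdensity(cbind(y$h, y$v), "R", pid1))
  expect_equal(forward_loglik(y, pid1), iid, tolerance = 1e-8)
  expect_equal(forward_loglik(y, pid2), iid, tolerance = 1e-8)
})

test_that("forward and smoothing match exhaustive enumeration on short paths", {
  set.seed(7)
  for (i in 1:20) {
    T <- sample(2:7, 1)
    p <- random_params()
    h <- rnorm(T, 3, 1.5); v <- rnorm(T, 3, 1.5)
    expect_equal(forward_loglik(list(h = h, v = v), p), enum_loglik(h, v, p),
                 tolerance = 1e-10)
    sm <- smooth_states(list(h = h, v = v), p)
    expect_equal(unname(sm), unname(enum_smoothed(h, v, p)),
                 tolerance = 1e-10)
    expect_equal(rowSums(sm), rep(1, T), tolerance = 1e-10)
  }
})

test_that("log posterior adds exactly the Beta and Gaussian prior terms", {
  set.seed(11)
  p <- hmm_parameters(0.99, 0.99, matrix(c(2, 2, 4, 4), 2, byrow = TRUE),
                      matrix(0.5, 2, 2), c(0, 0))
  path <- list(h = rnorm(40, 3), v = rnorm(40, 3))
  # flat Beta(1,1), no mean prior: identical to the likelihood
  expect_identical(log_posterior(path, p, transition_prior(1, 1)),
                   forward_loglik(path, p))
  # Beta(99,1) at gamma = 0.99: closed-form pdf 99 * 0.99^98 per state
  lp <- log_posterior(path, p, transition_prior(99, 1))
  expect_equal(lp - forward_loglik(path, p),
               2 * (log(99) + 98 * log(0.99)), tolerance = 1e-10)
  # Gaussian mean-prior terms with delta as a variance
  mp <- mean_prior_set("cod", matrix(c(2, 2, 4, 4), 2, byrow = TRUE),
                       matrix(0.04, 2, 2))
  lp2 <- log_posterior(path, p, transition_prior(99, 1), mp)
  expect_equal(lp2 - lp, sum(dnorm(c(2, 2, 4, 4), c(2, 2, 4, 4),
                                   sqrt(0.04), log = TRUE)),
               tolerance = 1e-10)
  expect_error(log_posterior(path, list(gamma_RR = 1.2), transition_prior()))
})

test_that("smoothing is symmetric when states are indistinguishable", {
  mu <- matrix(3, 2, 2); sg <- matrix(0.6, 2, 2)
  p <- hmm_parameters(0.9, 0.9, mu, sg, c(0.1, 0.1))
  set.seed(13)
  sm <- smooth_states(list(h = rnorm(25, 3), v = rnorm(25, 3)), p)
  expect_equal(unname(sm), matrix(0.5, 25, 2), tolerance = 1e-10)
})

test_that("decoding is invariant to relabelling both states", {
  set.seed(17)
  p <- random_params()
  h <- rnorm(50, 3, 1.5); v <- rnorm(50, 3, 1.5)
  sm <- smooth_states(list(h = h, v = v), p)
  sw <- smooth_states(list(h = h, v = v), fishHMM:::swap_state_labels(p))
  expect_equal(unname(sm), unname(sw[, c("M", "R")]), tolerance = 1e-12)
})

test_that("state allocation applies the 0.85 threshold and ties go to R", {
  sm <- cbind(R = c(0.9, 0.84, 0.5, 0.1), M = c(0.1, 0.16, 0.5, 0.9))
  a <- allocate_states(sm)
  expect_equal(a$state, c("R", "R", "R", "M"))
  expect_equal(a$uncertain, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("MAP fitting recovers parameters and flags data-poor failures", {
  sp <- well_sep_spec()
  f <- simulate_individual(sp, 400, seed = 101)
  fit <- fit_map(f$path, cfg = fit_config(n_restarts = 5))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$mu - f$params$mu)), 0.15)
  expect_lt(abs(fit$params$gamma_RR - f$params$gamma_RR), 0.015)
  expect_gt(mean(fit$states == f$states), 0.95)
  # unprimed label convention: resident has the smaller horizontal mean
  expect_lt(fit$params$mu["R", "H"], fit$params$mu["M", "H"])

  # T = 10 without priors: degenerate or non-converged is the expected mode
  f2 <- simulate_individual(sp, 10, seed = 102)
  fit2 <- fit_map(f2$path, cfg = fit_config(n_restarts = 5))
  mp <- mean_prior_set("cod", matrix(c(2, 2, 4, 4), 2, byrow = TRUE),
                       matrix(0.05, 2, 2))
  fit3 <- fit_map(f2$path, mp = mp, cfg = fit_config(n_restarts = 5))
  expect_true(fit3$converged)
  expect_gt(mean(fit3$states == f2$states), 0.8)
})

test_that("a stronger persistence prior never lowers the fitted self-transition", {
  sp <- well_sep_spec(gamma_fixed = 0.95)
  f <- simulate_individual(sp, 200, seed = 103)
  alphas <- c(4, 19, 99, 399)
  g <- vapply(alphas, function(a) {
    fit_map(f$path, tp = transition_prior(a, 1),
            cfg = fit_config(n_restarts = 3))$params$gamma_RR
  }, numeric(1))
  expect_true(all(diff(g) > -1e-6))
})

test_that("pseudo-residuals are standard normal under the model and detect shifts", {
  sp <- well_sep_spec()
  f <- simulate_individual(sp, 500, seed = 104)
  r <- pseudo_residuals(f$path, f$params)
  expect_equal(nrow(r), 500)
  expect_gt(shapiro.test(r$r_h)$p.value, 0.01)
  expect_gt(shapiro.test(r$r_v)$p.value, 0.01)
  expect_lt(abs(mean(r$r_h)), 0.2)

  shifted <- f$path; shifted$h <- shifted$h + 1.5
  r2 <- pseudo_residuals(shifted, f$params)
  expect_gt(mean(r2$r_h), 0.5)

  # T = 1 residual defined from the omega mixture CDF
  one <- list(h = 2.0, v = 2.0)
  r1 <- pseudo_residuals(one, f$params)
  u <- 0.5 * pnorm(2, f$params$mu["R", "H"], f$params$sigma["R", "H"]) +
    0.5 * pnorm(2, f$params$mu["M", "H"], f$params$sigma["M", "H"])
  expect_equal(r1$r_h, qnorm(u), tolerance = 1e-10)
})
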
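# The variational-Laplace engine is checked against conjugate linear-
# Gaussian results, where the Laplace bound is tight and closed forms exist.

linear_problem <- function(n, d, sigma, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n)
  theta <- rnorm(d, sd = 0.5)
  y <- as.numeric(X %*% theta + rnorm(n, sd = sigma))
  list(X = X, theta = theta, y = y, f = function(t) as.numeric(X %*% t))
}

exact_log_evidence <- function(X, y, mu0, S0, sigma) {
  n <- length(y)
  Sy <- X %*% S0 %*% t(X) + sigma^2 * diag(n)
  mu_y <- as.numeric(X %*% mu0)
  ld <- as.numeric(determinant(Sy)$modulus)
  -0.5 * (n * log(2 * pi) + ld +
            t(y - mu_y) %*% solve(Sy, y - mu_y))
}

test_that("free energy equals the conjugate log evidence for linear models", {
  pr <- linear_problem(50, 4, sigma = 0.4, seed = 91)
  mu0 <- rep(0, 4)
  S0 <- diag(0.7, 4)
  fit <- vl_invert(pr$f, pr$y, mu0, S0,
                   noise = list(fixed = TRUE, precision = 1 / 0.4^2),
                   max_iter = 200, tol = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$free_energy,
               as.numeric(exact_log_evidence(pr$X, pr$y, mu0, S0, 0.4)),
               tolerance = 1e-3)
  # posterior mean equals the ridge/Bayes closed form
  P <- crossprod(pr$X) / 0.4^2 + solve(S0)
  m_exact <- solve(P, crossprod(pr$X, pr$y) / 0.4^2)
  expect_equal(fit$mean, as.numeric(m_exact), tolerance = 1e-6)
  expect_equal(fit$cov, solve(P), tolerance = 1e-6)
})

test_that("free energy penalizes parameters that do not improve the fit", {
  # data from the smaller (1-parameter) model; larger model adds 3 junk
  # columns. Occam: F(small) > F(large) in >= 90 % of replicates.
  wins <- 0L
  n_rep <- 100L
  set.seed(92)
  for (r in seq_len(n_rep)) {
    n <- 60
    x1 <- rnorm(n)
    Xbig <- cbind(x1, matrix(rnorm(n * 3), n))
    y <- 0.8 * x1 + rnorm(n, sd = 0.5)
    fs <- vl_invert(function(t) 0 + x1 * t, y, 0, diag(1, 1),
                    noise = list(fixed = TRUE, precision = 4),
                    max_iter = 50, tol = 1e-6)
    fb <- vl_invert(function(t) as.numeric(Xbig %*% t), y, rep(0, 4),
                    diag(1, 4), noise = list(fixed = TRUE, precision = 4),
                    max_iter = 50, tol = 1e-6)
    wins <- wins + (fs$free_energy > fb$free_energy)
  }
  expect_gte(wins, 90L)
})

test_that("a near-delta prior pins the posterior and F at the prior mean", {
  pr <- linear_problem(40, 3, sigma = 0.5, seed = 93)
  mu0 <- c(0.2, -0.1, 0.3)
  fit <- vl_invert(pr$f, pr$y, mu0, diag(1e-10, 3),
                   noise = list(fixed = TRUE, precision = 4),
                   max_iter = 50, tol = 1e-8)
  expect_lt(max(abs(fit$mean - mu0)), 1e-4)
  loglik_at_mu0 <- sum(dnorm(pr$y, as.numeric(pr$X %*% mu0), 0.5, log = TRUE))
  expect_equal(fit$free_energy, loglik_at_mu0, tolerance = 1e-3)
})

test_that("data equal to the prior-mean prediction is a fixed point", {
  set.seed(94)
  X <- matrix(rnorm(30 * 3), 30)
  mu0 <- c(0.4, -0.2, 0.1)
  y <- as.numeric(X %*% mu0) # exact prior-mean prediction, no noise
  fit <- vl_invert(function(t) as.numeric(X %*% t), y, mu0, diag(0.5, 3),
                   max_iter = 100, tol = 1e-8)
  expect_lt(sqrt(sum((fit$mean - mu0)^2)), 1e-3)
})

test_that("estimated noise precision converges near the truth", {
  pr <- linear_problem(400, 3, sigma = 0.5, seed = 95)
  fit <- vl_invert(pr$f, pr$y, rep(0, 3), diag(1, 3),
                   noise = list(shape = 2, rate = 1),
                   max_iter = 100, tol = 1e-6)
  expect_lt(abs(fit$precision - 4) / 4, 0.25)
})

test_that("vl_free_energy agrees with vl_invert at its own posterior", {
  pr <- linear_problem(30, 3, sigma = 0.5, seed = 96)
  nz <- list(fixed = TRUE, precision = 4)
  fit <- vl_invert(pr$f, pr$y, rep(0, 3), diag(1, 3), noise = nz,
                   max_iter = 100, tol = 1e-8)
  F2 <- vl_free_energy(pr$f, pr$y, list(mean = fit$mean, cov = fit$cov),
                       rep(0, 3), diag(1, 3), noise = nz)
  expect_equal(F2, fit$free_energy, tolerance = 1e-6)
})
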
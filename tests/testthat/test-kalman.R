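test_that("scalar forward/backward passes match the full-matrix oracle", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(30:200, 1)
    omega0 <- runif(1, 0.05, 3)
    sigma <- runif(1, 0.05, 2)
    alpha <- runif(1, 0.05, 2)
    obs <- complex(real = rnorm(n), imaginary = rnorm(n))
    fr <- forward_pass(obs, omega0, sigma, alpha)
    sm <- backward_pass(fr)
    o <- matrix_kalman(obs, omega0, sigma, alpha)
    expect_lt(max(abs(Re(fr$filtered_means) - o$filtered_means[1, ])), 1e-10)
    expect_lt(max(abs(Im(fr$filtered_means) - o$filtered_means[2, ])), 1e-10)
    expect_lt(max(abs(fr$filtered_vars - o$filtered_covs[1, 1, ])), 1e-10)
    expect_lt(max(abs(o$filtered_covs[1, 2, ])), 1e-10) # stays diagonal
    expect_lt(max(abs(Re(sm$smoothed_means) - o$smoothed_means[1, ])), 1e-10)
    expect_lt(max(abs(Im(sm$smoothed_means) - o$smoothed_means[2, ])), 1e-10)
    expect_lt(max(abs(sm$smoothed_vars - o$smoothed_covs[1, 1, ])), 1e-10)
  }
})

test_that("huge measurement noise reduces the filter to pure prediction", {
  set.seed(30)
  n <- 200
  omega0 <- 0.3
  sigma <- 1
  obs <- complex(real = rnorm(n), imaginary = rnorm(n))
  fr <- forward_pass(obs, omega0, sigma, alpha = 1e12 * sigma, p1 = sigma)
  expect_true(all(fr$gains[-1] < 1e-5))
  rot <- complex(argument = omega0)
  pred <- fr$filtered_means[1] * rot^(0:(n - 1))
  expect_lt(max(Mod(fr$filtered_means - pred)), 1e-2)
})

test_that("noiseless rotating observations are tracked exactly when sigma = 0", {
  omega0 <- 0.4
  obs <- complex(argument = omega0 * (0:499))
  fr <- forward_pass(obs, omega0, sigma = 0, alpha = 0.5)
  expect_lt(max(Mod(fr$filtered_means - obs)), 1e-6)
  expect_lt(fr$filtered_vars[500], 1e-2) # p -> p* = 0 like alpha/t
  sm <- backward_pass(fr)
  expect_lt(max(Mod(sm$smoothed_means - obs)), 1e-6)
})

test_that("filtered variance converges to the Riccati fixed point", {
  set.seed(5)
  for (k in 1:5) {
    sigma <- runif(1, 0.1, 2)
    alpha <- runif(1, 0.1, 2)
    obs <- complex(real = rnorm(500), imaginary = rnorm(500))
    fr <- forward_pass(obs, 0.2, sigma, alpha)
    p_star <- riccati_fixed_point(sigma, alpha)
    expect_equal(fr$filtered_vars[500], p_star, tolerance = 1e-9)
    # p* solves the variance recursion
    expect_equal((p_star + sigma) * alpha / (p_star + sigma + alpha), p_star,
                 tolerance = 1e-12)
  }
})

test_that("smoothing never increases the posterior variance", {
  set.seed(6)
  for (k in 1:50) {
    sigma <- runif(1, 0.01, 2)
    alpha <- runif(1, 0.01, 2)
    n <- sample(20:120, 1)
    obs <- complex(real = rnorm(n), imaginary = rnorm(n))
    sm <- backward_pass(forward_pass(obs, runif(1, 0, 3), sigma, alpha))
    expect_true(all(sm$smoothed_vars <= sm$filtered_vars + 1e-12))
    expect_equal(sm$smoothed_means[n], sm$filtered_means[n])
    expect_equal(sm$smoothed_vars[n], sm$filtered_vars[n])
  }
})

test_that("the smoother is the identity on a pure rotation in the noise-free limit", {
  omega0 <- 0.7
  obs <- complex(argument = omega0 * (0:199))
  sm <- backward_pass(forward_pass(obs, omega0, sigma = 0, alpha = 0))
  expect_equal(sm$smoothed_means, obs, tolerance = 1e-12)
})

test_that("degenerate all-zero variance model is rejected", {
  obs <- complex(real = 1:5, imaginary = 0)
  expect_error(forward_pass(obs, 0.1, sigma = 0, alpha = 0, p1 = 0),
               "degenerate")
  expect_error(forward_pass(obs, 0.1, sigma = -1, alpha = 1), "sigma")
})

test_that("estimate_sigma recovers moments of the exact state model", {
  sim <- simulate_state_model(20000, omega0 = 0.3, sigma = 1, alpha = 0.5,
                              seed = 2)
  est <- estimate_sigma(sim$obs, omega0 = 0.3, alpha = 0.5)
  expect_equal(est$epsilon, 1 + 2 * 0.5, tolerance = 0.05)
  expect_equal(est$sigma_hat, 1, tolerance = 0.1)
  expect_equal(est$sigma_range[2], est$epsilon)
})

test_that("estimate_sigma honours its conventions", {
  sim <- simulate_state_model(500, 0.2, 0.5, 0.1, seed = 3)
  # alpha = 0: the range upper bound is epsilon itself
  e0 <- estimate_sigma(sim$obs, 0.2, alpha = 0)
  expect_equal(e0$sigma_range, c(e0$epsilon, e0$epsilon))
  # beta = 0 gives sigma_point = 0 (full smoothing)
  expect_identical(estimate_sigma(sim$obs, 0.2, alpha = 0.1, beta = 0)$sigma_point, 0)
  # constant observations warn and give a zero range
  expect_warning(ec <- estimate_sigma(rep(complex(real = 1), 10), 0),
                 "constant")
  expect_equal(ec$sigma_range, c(0, 0))
  expect_error(estimate_sigma(sim$obs[1:2], 0.2), "length")
})

test_that("estimate_alpha measures cross-member spread correctly", {
  set.seed(8)
  n <- 400
  common <- complex(real = rnorm(n), imaginary = rnorm(n))
  v <- 0.3
  members <- vapply(1:40, function(m) {
    common + complex(real = rnorm(n, 0, sqrt(v)),
                     imaginary = rnorm(n, 0, sqrt(v)))
  }, complex(n))
  expect_equal(estimate_alpha(members), v, tolerance = 0.05)
  # translation invariance
  shifted <- members + complex(real = 5, imaginary = -2)
  expect_equal(estimate_alpha(shifted), estimate_alpha(members),
               tolerance = 1e-12)
  # identical members have zero spread
  same <- vapply(1:5, function(m) common, complex(n))
  expect_equal(estimate_alpha(same), 0)
  expect_error(estimate_alpha(same[, 1, drop = FALSE]), "2 ensemble members")
})

test_that("smooth_phase flattens a pure tone and is deterministic", {
  fs <- 250
  t <- (0:2999) / fs
  x <- sin(2 * pi * 10 * t)
  s1 <- smooth_phase(x, fc = 10, fs = fs, bandwidth = 4, M = 8, seed = 21)
  s2 <- smooth_phase(x, fc = 10, fs = fs, bandwidth = 4, M = 8, seed = 21)
  expect_identical(s1$smoothed_means, s2$smoothed_means)
  td <- tidy(s1)
  interior <- !td$edge
  expect_lte(max(abs(td$residual_post[interior] -
                     median(td$residual_post[interior]))),
             max(abs(td$residual_pre[interior] -
                     median(td$residual_pre[interior]))) + 1e-12)
})

test_that("smooth_phase errors carry their stage tag", {
  x <- rnorm(3000)
  expect_error(smooth_phase(x, fc = 200, fs = 250, bandwidth = 4, M = 2,
                            seed = 1),
               "\\[ensemble_filter\\]")
  expect_error(smooth_phase(x[1:100], fc = 10, fs = 250, bandwidth = 4),
               "too short")
})
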
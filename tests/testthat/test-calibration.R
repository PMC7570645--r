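test_that("fit_gaussian computes the mean and the unbiased covariance", {
  s <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  fit <- fit_gaussian(s)
  expect_equal(fit$mu, c(0, 0, 0))
  # hand-derived: each axis has sum of squares 2 over divisor N - 1 = 5
  expect_equal(fit$sigma, diag(2 / 5, 3), tolerance = 1e-14)
  expect_false(fit$ridged)
})

test_that("fit_gaussian rejects too-few or non-finite samples", {
  expect_error(fit_gaussian(matrix(rnorm(9), 3)), class = "pw_insufficient_data")
  bad <- matrix(rnorm(15), 5)
  bad[2, 3] <- NaN
  expect_error(fit_gaussian(bad), class = "pw_invalid_data")
})

test_that("degenerate covariance is ridge-regularized and flagged", {
  s <- matrix(rep(c(1, 2, 3), each = 10), 10)  # constant samples, zero covariance
  fit <- fit_gaussian(s)
  expect_true(fit$ridged)
  expect_true(all(eigen(fit$sigma, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_silent(compute_threshold(fit$mu, fit$sigma, 0.95))
})

test_that("fit_gaussian recovers generating parameters with shrinking error", {
  skip_if_not_installed("MASS")
  set.seed(42)
  mu_star <- c(2, -1, 5)
  sigma_star <- rand_spd()
  err <- vapply(c(1e3, 1e4, 1e5), function(n) {
    x <- MASS::mvrnorm(n, mu_star, sigma_star)
    fit <- fit_gaussian(x)
    sqrt(sum((fit$mu - mu_star)^2))
  }, numeric(1))
  # mean error shrinks roughly as 1/sqrt(n); demand monotone decrease
  expect_true(all(diff(err) < 0))
  # at n = 1e4, each component within 3 standard errors
  x <- MASS::mvrnorm(1e4, mu_star, sigma_star)
  fit <- fit_gaussian(x)
  se <- sqrt(diag(sigma_star) / 1e4)
  expect_true(all(abs(fit$mu - mu_star) < 3 * se))
})

test_that("gaussian_density matches closed forms and a brute-force oracle", {
  expect_equal(gaussian_density(c(0, 0, 0), c(0, 0, 0), diag(3)),
               (2 * pi)^(-3 / 2), tolerance = 1e-12)
  # isotropic: density decays as exp(-d^2/2)
  x <- c(1, 2, 2)  # |x| = 3
  expect_equal(gaussian_density(x, c(0, 0, 0), diag(3)),
               (2 * pi)^(-3 / 2) * exp(-9 / 2), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    sigma <- rand_spd()
    mu <- rnorm(3)
    x <- rnorm(3, sd = 3)
    # independent route: explicit inverse and determinant
    brute <- (2 * pi)^(-3 / 2) * det(sigma)^(-1 / 2) *
      exp(-0.5 * t(x - mu) %*% solve(sigma) %*% (x - mu))
    expect_equal(gaussian_density(x, mu, sigma), as.numeric(brute),
                 tolerance = 1e-10)
  }
})

test_that("gaussian_density rejects singular covariance", {
  sigma <- diag(c(1, 1, 0))
  expect_error(gaussian_density(c(0, 0, 0), c(0, 0, 0), sigma),
               class = "pw_numeric_degeneracy")
})

test_that("confidence offsets reach the chi-squared quantile on every axis", {
  # isotropic case at the confidence level whose chi2(3) quantile is 1
  conf1 <- pchisq(1, df = 3)
  off <- confidence_offsets(diag(3), conf1)
  expect_equal(apply(off$delta, 2, function(d) sqrt(sum(d^2))), rep(1, 3),
               tolerance = 1e-12)
  # eigenvalue scaling: axis lengths scale as sqrt(lambda)
  off <- confidence_offsets(diag(c(4, 1, 1)), 0.95)
  lens <- sort(apply(off$delta, 2, function(d) sqrt(sum(d^2))), decreasing = TRUE)
  expect_equal(lens[1], 2 * lens[2], tolerance = 1e-12)
  # quantile oracle on random SPD matrices via stats::mahalanobis
  set.seed(11)
  q95 <- qchisq(0.95, df = 3)
  for (i in 1:10) {
    sigma <- rand_spd()
    mu <- rnorm(3)
    off <- confidence_offsets(sigma, 0.95)
    for (j in 1:3) {
      expect_equal(as.numeric(stats::mahalanobis(mu + off$delta[, j], mu, sigma)),
                   q95, tolerance = 1e-9)
    }
    # eigvecs orthonormal
    expect_equal(crossprod(off$eigvecs), diag(3), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("confidence level outside (0,1) is rejected", {
  expect_error(confidence_offsets(diag(3), 0), class = "pw_invalid_parameter")
  expect_error(confidence_offsets(diag(3), 1), class = "pw_invalid_parameter")
  expect_error(compute_threshold(rep(0, 3), diag(3), 1.2), class = "pw_invalid_parameter")
})

test_that("threshold is axis-independent and matches the ellipsoid endpoint density", {
  set.seed(5)
  for (i in 1:10) {
    sigma <- rand_spd()
    mu <- rnorm(3)
    tau <- compute_threshold(mu, sigma, 0.95)
    off <- confidence_offsets(sigma, 0.95)
    endpoint_tau <- vapply(1:3, function(j) {
      gaussian_density(mu + off$delta[, j], mu, sigma)
    }, numeric(1))
    expect_true(all(abs(endpoint_tau - tau) / tau < 1e-10))
  }
})

test_that("threshold approaches the density at the mean as the region shrinks", {
  sigma <- rand_spd()
  mu <- c(1, 2, 3)
  expect_equal(compute_threshold(mu, sigma, 1e-12),
               gaussian_density(mu, mu, sigma), tolerance = 1e-6)
})

test_that("fraction of in-model draws with density >= tau converges to c", {
  skip_if_not_installed("MASS")
  set.seed(13)
  sigma <- rand_spd()
  mu <- c(-1, 4, 2)
  fit <- fit_gaussian(MASS::mvrnorm(1000, mu, sigma))
  tau <- compute_threshold(fit$mu, fit$sigma, 0.95)
  x <- MASS::mvrnorm(20000, fit$mu, fit$sigma)
  cover <- mean(gaussian_density(x, fit$mu, fit$sigma) >= tau)
  band <- 5 * sqrt(0.95 * 0.05 / 20000)
  expect_gt(cover, 0.95 - band)
  expect_lt(cover, 0.95 + band)
})

test_that("acceptance region is equivariant under invertible linear maps", {
  skip_if_not_installed("MASS")
  set.seed(17)
  sigma <- rand_spd()
  mu <- c(1, -2, 0.5)
  x <- MASS::mvrnorm(500, mu, sigma)
  A <- matrix(c(2, 0.3, -0.1, 0.1, 1.5, 0.4, 0, -0.2, 0.8), 3L)
  fit <- fit_gaussian(x)
  fit_A <- fit_gaussian(x %*% t(A))
  tau <- compute_threshold(fit$mu, fit$sigma, 0.95)
  tau_A <- compute_threshold(fit_A$mu, fit_A$sigma, 0.95)
  pts <- MASS::mvrnorm(500, mu, 4 * sigma)
  acc <- gaussian_density(pts, fit$mu, fit$sigma) >= tau
  acc_A <- gaussian_density(pts %*% t(A), fit_A$mu, fit_A$sigma) >= tau_A
  expect_identical(acc, acc_A)
})

test_that("calibrate builds one region per (sensor, pose) with positive thresholds", {
  sets <- simulate_calibration(physics_config(), n_per_pose = 50, seed = 3)
  model <- calibrate(sets)
  expect_s3_class(model, "calibration_model")
  expect_length(model$regions, 16L)
  expect_true(all(vapply(model$regions, function(r) r$tau, numeric(1)) > 0))
  expect_equal(unique(vapply(model$regions, function(r) r$conf, numeric(1))), 0.95)
  # single pose set degenerates to a single-ellipsoid test
  one <- calibrate(sets[1])
  expect_length(one$regions, 1L)
  expect_equal(classify_point(one$regions[[1]]$mu, one, "accelerometer"), "correct")
})

test_that("calibrate rejects empty and malformed input", {
  expect_error(calibrate(list()), class = "pw_insufficient_data")
  expect_error(calibrate(list(list(pose_label = "p"))), class = "pw_invalid_data")
})

test_that("calibrated regions recover their generating Gaussians", {
  skip_if_not_installed("MASS")
  set.seed(23)
  gen <- list(list(mu = c(0, 0, 9.8), sigma = rand_spd(0.1)),
              list(mu = c(2000, 300, -400), sigma = 100 * rand_spd()))
  sets <- list(
    list(pose_label = "a", sensor = "accelerometer",
         samples = MASS::mvrnorm(5000, gen[[1]]$mu, gen[[1]]$sigma)),
    list(pose_label = "a", sensor = "magnetometer",
         samples = MASS::mvrnorm(5000, gen[[2]]$mu, gen[[2]]$sigma)))
  model <- calibrate(sets)
  for (i in 1:2) {
    r <- model$regions[[i]]
    g <- gen[[i]]
    se <- sqrt(diag(g$sigma) / 5000)
    expect_true(all(abs(r$mu - g$mu) < 4 * se))
    expect_lt(norm(r$sigma - g$sigma, "F") / norm(g$sigma, "F"), 0.1)
  }
})
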
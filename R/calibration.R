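#' Fit a trivariate Gaussian to calibration samples
#'
#' Estimates the mean vector and the unbiased (divisor N-1) sample covariance
#' of a set of 3-axis sensor readings recorded while a calibration pose is
#' held. The covariance is symmetrized; if it is singular or its condition
#' number exceeds `max_condition`, a diagonal ridge of
#' `ridge_epsilon * trace(sigma) / 3` is added so that noiseless or degenerate
#' recordings still yield a usable (if inflated) region, and the fit is
#' flagged as ridged.
#'
#' @param samples numeric matrix with one 3-axis reading per row (N >= 4).
#' @param ridge_epsilon relative ridge added to the diagonal when the
#'   covariance is degenerate.
#' @param max_condition condition-number bound above which the ridge is applied.
#' @return list with `mu` (length-3 mean), `sigma` (3x3 covariance) and
#'   `ridged` (logical, TRUE when regularization was applied).
#' @examples
#' s <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
#' fit_gaussian(s)
#' @export
fit_gaussian <- function(samples, ridge_epsilon = 1e-6, max_condition = 1e12) {
  samples <- as_samples(samples)
  n <- nrow(samples)
  if (n < 4L) {
    pw_error("pw_insufficient_data",
             sprintf("need at least 4 samples for a full-rank 3-D covariance, got %d", n))
  }
  mu <- colMeans(samples)
  sigma <- stats::cov(samples)
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  ridged <- FALSE
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > max_condition) {
    ridge <- ridge_epsilon * sum(diag(sigma)) / 3
    if (ridge <= 0) ridge <- ridge_epsilon  # all-constant samples: trace is zero
    sigma <- sigma + diag(ridge, 3L)
    ridged <- TRUE
  }
  list(mu = as.numeric(mu), sigma = sigma, ridged = ridged)
}

# Cholesky factor with a classed error on non-SPD input.
chol_spd <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8))) {
    pw_error("pw_invalid_data", "covariance matrix must be symmetric")
  }
  tryCatch(chol(sigma),
           error = function(e) pw_error("pw_numeric_degeneracy",
                                        "covariance matrix is singular or not positive definite"))
}

#' Trivariate Gaussian density
#'
#' Evaluates the trivariate normal density
#' \deqn{N(x; \mu, \Sigma) = (2\pi)^{-3/2} |\Sigma|^{-1/2}
#'       e^{-\frac{1}{2}(x-\mu)^T \Sigma^{-1} (x-\mu)}}
#' via a Cholesky factorization of the covariance.
#'
#' @param x a 3-vector or an n x 3 matrix of evaluation points.
#' @param mu length-3 mean vector.
#' @param sigma 3x3 symmetric positive-definite covariance.
#' @return numeric vector of densities (length 1 for a single point).
#' @export
gaussian_density <- function(x, mu, sigma) {
  x <- as_samples(x, "evaluation points")
  R <- chol_spd(sigma)
  log_det <- 2 * sum(log(diag(R)))
  centered <- t(x) - as.numeric(mu)
  z <- backsolve(R, centered, transpose = TRUE)
  maha2 <- colSums(z^2)
  as.numeric(exp(-0.5 * (3 * log(2 * pi) + log_det + maha2)))
}

# Squared Mahalanobis distance of rows of x from mu under sigma.
mahalanobis2 <- function(x, mu, sigma) {
  x <- as_samples(x, "evaluation points")
  R <- chol_spd(sigma)
  z <- backsolve(R, t(x) - as.numeric(mu), transpose = TRUE)
  colSums(z^2)
}

#' Confidence-ellipsoid semi-axis offsets
#'
#' For a covariance `sigma` and confidence level `c`, returns the three
#' offset vectors from the mean to the surface of the c-level confidence
#' ellipsoid along its principal axes: `delta_j = sqrt(q * lambda_j) * v_j`,
#' where `q` is the chi-squared quantile with 3 degrees of freedom at `c` and
#' `(lambda_j, v_j)` are the eigenpairs of `sigma`. Each endpoint
#' `mu + delta_j` sits at squared Mahalanobis distance exactly `q`.
#'
#' @param sigma 3x3 SPD covariance matrix.
#' @param conf confidence level in (0, 1).
#' @return list with `delta` (3x3 matrix, one offset vector per column),
#'   `eigvals` (length-3) and `eigvecs` (3x3, orthonormal columns).
#' @export
confidence_offsets <- function(sigma, conf = 0.95) {
  if (!is.numeric(conf) || length(conf) != 1L || is.na(conf) || conf <= 0 || conf >= 1) {
    pw_error("pw_invalid_parameter", "confidence level must lie strictly between 0 and 1")
  }
  e <- eigen(as.matrix(sigma), symmetric = TRUE)
  if (min(e$values) <= 0) {
    pw_error("pw_numeric_degeneracy", "covariance matrix is not positive definite")
  }
  q <- stats::qchisq(conf, df = 3)
  delta <- e$vectors %*% diag(sqrt(q * e$values), 3L)
  list(delta = delta, eigvals = e$values, eigvecs = e$vectors)
}

#' Density threshold of a confidence region
#'
#' The threshold `tau` is the Gaussian density on the surface of the c-level
#' confidence ellipsoid. All three semi-axis endpoints `mu + delta_j` are
#' isodense, so `tau` is computed by the closed form
#' `(2*pi)^(-3/2) * |sigma|^(-1/2) * exp(-q/2)` with `q` the chi-squared
#' (3 df) quantile at `conf`; points with density at or above `tau` lie inside
#' the closed region, which covers probability `conf` of the fitted Gaussian.
#'
#' @inheritParams confidence_offsets
#' @param mu length-3 mean vector (unused by the closed form; kept so the
#'   signature mirrors the endpoint construction).
#' @return positive scalar density threshold.
#' @export
compute_threshold <- function(mu, sigma, conf = 0.95) {
  if (!is.numeric(conf) || length(conf) != 1L || is.na(conf) || conf <= 0 || conf >= 1) {
    pw_error("pw_invalid_parameter", "confidence level must lie strictly between 0 and 1")
  }
  R <- chol_spd(sigma)
  log_det <- 2 * sum(log(diag(R)))
  q <- stats::qchisq(conf, df = 3)
  exp(-0.5 * (3 * log(2 * pi) + log_det + q))
}

#' Build a single calibrated Gaussian region
#'
#' Fits the Gaussian, derives the principal-axis offsets and the density
#' threshold for one (sensor, pose) calibration set.
#'
#' @param samples n x 3 matrix of readings for one held pose (n >= 4).
#' @param pose_label character label of the calibration pose,
#'   e.g. `"standing.arms_down"`.
#' @param sensor `"accelerometer"` or `"magnetometer"`.
#' @param conf confidence level in (0, 1).
#' @param ... passed to [fit_gaussian()].
#' @return object of class `gaussian_region` with fields `mu`, `sigma`, `conf`,
#'   `tau`, `eigvals`, `eigvecs`, `delta`, `pose_label`, `sensor`, `ridged`.
#' @export
gaussian_region <- function(samples, pose_label, sensor, conf = 0.95, ...) {
  sensor <- check_sensor(sensor)
  fit <- fit_gaussian(samples, ...)
  off <- confidence_offsets(fit$sigma, conf)
  structure(list(
    mu = fit$mu,
    sigma = fit$sigma,
    conf = conf,
    tau = compute_threshold(fit$mu, fit$sigma, conf),
    eigvals = off$eigvals,
    eigvecs = off$eigvecs,
    delta = off$delta,
    pose_label = as.character(pose_label),
    sensor = sensor,
    ridged = fit$ridged
  ), class = "gaussian_region")
}

#' @export
print.gaussian_region <- function(x, ...) {
  cat(sprintf("<gaussian_region> %s / %s  (c = %g%s)\n",
              x$sensor, x$pose_label, x$conf, if (x$ridged) ", ridged" else ""))
  cat("  mu:  ", paste(signif(x$mu, 5), collapse = "  "), "\n")
  cat("  tau: ", signif(x$tau, 5), "\n")
  invisible(x)
}

#' Calibrate a posture model from labelled pose sets
#'
#' Fits one Gaussian confidence region per (sensor, pose) calibration set.
#' The canonical protocol uses eight poses — standing/sitting crossed with
#' four arm configurations, all held with a correct posture — recorded for
#' both the accelerometer and the magnetometer, giving 16 regions.
#'
#' @param pose_sets list of pose sets; each is a list with `pose_label`,
#'   `sensor`, and `samples` (n x 3 matrix), as produced by
#'   [simulate_calibration()] or read from a pose-tagged trace file.
#' @param conf shared confidence level (default 0.95).
#' @param units named list of unit strings per sensor; defaults to
#'   m/s^2 for the accelerometer and microtesla for the magnetometer.
#' @param ... passed to [gaussian_region()].
#' @return object of class `calibration_model`: list with `regions` (named
#'   list of `gaussian_region`, keyed `<sensor>:<pose_label>`), `conf`, `units`.
#' @export
calibrate <- function(pose_sets, conf = 0.95,
                      units = list(accelerometer = "m/s2", magnetometer = "uT"),
                      ...) {
  if (length(pose_sets) == 0L) {
    pw_error("pw_insufficient_data", "no calibration pose sets supplied")
  }
  regions <- list()
  for (ps in pose_sets) {
    if (is.null(ps$pose_label) || is.null(ps$sensor) || is.null(ps$samples)) {
      pw_error("pw_invalid_data",
               "each pose set needs fields 'pose_label', 'sensor' and 'samples'")
    }
    key <- paste(ps$sensor, ps$pose_label, sep = ":")
    if (!is.null(regions[[key]])) {
      pw_error("pw_invalid_data", sprintf("duplicate calibration set '%s'", key))
    }
    regions[[key]] <- gaussian_region(ps$samples, ps$pose_label, ps$sensor, conf, ...)
  }
  structure(list(regions = regions, conf = conf, units = units),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  sensors <- vapply(x$regions, function(r) r$sensor, character(1))
  cat(sprintf("<calibration_model> %d regions (c = %g)\n", length(x$regions), x$conf))
  for (s in unique(sensors)) {
    cat(sprintf("  %s: %d pose regions [%s]\n", s, sum(sensors == s), x$units[[s]] %||% "?"))
  }
  invisible(x)
}

# Regions of a model belonging to one sensor.
model_regions <- function(model, sensor) {
  sensor <- check_sensor(sensor)
  Filter(function(r) r$sensor == sensor, model$regions)
}
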
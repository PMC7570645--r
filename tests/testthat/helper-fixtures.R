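# Shared fixtures: random SPD matrices and hand-built calibration models.

rand_spd <- function(scale = 1) {
  A <- matrix(stats::rnorm(9), 3L)
  crossprod(A) + diag(0.1 * scale, 3L)
}

# Region built directly from known parameters (no fitting step), so tests
# can compare against oracles computed from the same mu/sigma.
make_region <- function(mu, sigma, conf = 0.95, pose_label = "pose",
                        sensor = "accelerometer") {
  off <- confidence_offsets(sigma, conf)
  structure(list(mu = mu, sigma = sigma, conf = conf,
                 tau = compute_threshold(mu, sigma, conf),
                 eigvals = off$eigvals, eigvecs = off$eigvecs,
                 delta = off$delta, pose_label = pose_label, sensor = sensor,
                 ridged = FALSE),
            class = "gaussian_region")
}

make_model <- function(regions, conf = 0.95) {
  names(regions) <- vapply(regions, function(r) paste(r$sensor, r$pose_label, sep = ":"),
                           character(1))
  structure(list(regions = regions, conf = conf,
                 units = list(accelerometer = "m/s2", magnetometer = "uT")),
            class = "calibration_model")
}

rand_model <- function(n_regions = 3, conf = 0.95, sensor = "accelerometer",
                       spread = 20) {
  regions <- lapply(seq_len(n_regions), function(i) {
    make_region(stats::runif(3, -spread, spread), rand_spd(), conf,
                pose_label = paste0("pose", i), sensor = sensor)
  })
  make_model(regions, conf)
}

# Minimum squared Mahalanobis distance of rows of x over a model's regions —
# the independent classification oracle (stats::mahalanobis, not the
# package's Cholesky path).
min_mahal2 <- function(x, model, sensor) {
  regions <- Filter(function(r) r$sensor == sensor, model$regions)
  d2 <- sapply(regions, function(r) stats::mahalanobis(x, r$mu, r$sigma))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
  apply(d2, 1L, min)
}
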
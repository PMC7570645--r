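#' Classify sensor readings against a calibration model
#'
#' A reading is labelled `"correct"` when it falls inside the confidence
#' region of at least one calibration pose for that sensor, i.e. when its
#' Gaussian density under some region meets or exceeds that region's density
#' threshold `tau` (the region is closed: a boundary tie counts as inside).
#' The eight pose clusters are spatially disjoint, so membership in the union
#' of regions is the operative test; `mode = "all"` requires membership in
#' every region and is provided for comparison only.
#'
#' @param x a 3-vector or n x 3 matrix of readings, in the model's units for
#'   that sensor.
#' @param model a [calibrate()]d `calibration_model`.
#' @param sensor `"accelerometer"` or `"magnetometer"`.
#' @param mode `"any"` (union of regions, default) or `"all"` (intersection).
#' @return character vector of `"correct"` / `"incorrect"`, one per reading.
#' @export
classify_point <- function(x, model, sensor, mode = c("any", "all")) {
  mode <- match.arg(mode)
  regions <- model_regions(model, sensor)
  if (length(regions) == 0L) {
    pw_error("pw_invalid_parameter",
             sprintf("model has no calibrated regions for sensor '%s'", sensor))
  }
  x <- as_samples(x, "readings")
  inside <- matrix(FALSE, nrow(x), length(regions))
  for (j in seq_along(regions)) {
    r <- regions[[j]]
    inside[, j] <- gaussian_density(x, r$mu, r$sigma) >= r$tau
  }
  hit <- if (mode == "any") rowSums(inside) > 0 else rowSums(inside) == ncol(inside)
  ifelse(hit, "correct", "incorrect")
}

#' Fuse the two per-sensor posture verdicts
#'
#' Implements the dual-sensor truth table: the fused posture is `"incorrect"`
#' only when both the accelerometer-based and the magnetometer-based
#' classifiers say incorrect; in every other case it is `"correct"`. A missing
#' verdict (`NA`, e.g. an unpaired sample) degrades to the remaining sensor.
#'
#' @param acc,mag character vectors of `"correct"`/`"incorrect"` (or `NA`),
#'   recycled to a common length.
#' @return character vector of fused labels.
#' @examples
#' fuse_labels(c("incorrect", "incorrect", "correct", "correct"),
#'             c("incorrect", "correct", "incorrect", "correct"))
#' @export
fuse_labels <- function(acc, mag) {
  acc <- check_labels(acc, "accelerometer labels")
  mag <- check_labels(mag, "magnetometer labels")
  n <- max(length(acc), length(mag))
  acc <- rep_len(acc, n)
  mag <- rep_len(mag, n)
  fused <- ifelse(acc == "incorrect" & mag == "incorrect", "incorrect", "correct")
  fused[is.na(acc) & is.na(mag)] <- NA_character_
  fused[is.na(acc) & !is.na(mag)] <- mag[is.na(acc) & !is.na(mag)]
  fused[!is.na(acc) & is.na(mag)] <- acc[!is.na(acc) & is.na(mag)]
  fused
}

# Index of the nearest value of `grid` (sorted) for each element of `t`.
nearest_index <- function(t, grid) {
  lo <- findInterval(t, grid)
  lo[lo < 1L] <- 1L
  hi <- pmin(lo + 1L, length(grid))
  ifelse(abs(grid[hi] - t) < abs(grid[lo] - t), hi, lo)
}

#' Classify paired accelerometer/magnetometer streams
#'
#' Classifies each sample of each trace against the model, pairs the two
#' streams by nearest timestamp within `pairing_tol`, fuses the paired
#' verdicts, and returns one record per time step in time order. Samples with
#' no partner within tolerance degrade to single-sensor fusion (the missing
#' label is `NA` and the record is flagged unpaired) rather than being
#' dropped, so the session-score denominator is preserved.
#'
#' @param acc_trace,mag_trace data frames with columns `t`, `x`, `y`, `z`
#'   (either may be `NULL` for single-sensor operation).
#' @param model a `calibration_model` covering the sensors present.
#' @param pairing_tol maximum timestamp mismatch (seconds) for pairing;
#'   default is half the median sampling period of the accelerometer trace.
#' @param mode region-combination mode, see [classify_point()].
#' @return data frame with columns `t`, `acc_label`, `mag_label`,
#'   `fused_label`, `paired`.
#' @export
classify_stream <- function(acc_trace = NULL, mag_trace = NULL, model,
                            pairing_tol = NULL, mode = c("any", "all")) {
  mode <- match.arg(mode)
  empty <- function(tr) is.null(tr) || nrow(tr) == 0L
  if (empty(acc_trace) && empty(mag_trace)) {
    warning("both traces are empty; returning no classification records")
    return(data.frame(t = numeric(0), acc_label = character(0),
                      mag_label = character(0), fused_label = character(0),
                      paired = logical(0), stringsAsFactors = FALSE))
  }
  trace_mat <- function(tr) as_samples(as.matrix(tr[, c("x", "y", "z")]), "trace readings")

  if (empty(mag_trace) || empty(acc_trace)) {
    tr <- if (empty(mag_trace)) acc_trace else mag_trace
    sensor <- if (empty(mag_trace)) "accelerometer" else "magnetometer"
    lab <- classify_point(trace_mat(tr), model, sensor, mode)
    out <- data.frame(t = tr$t,
                      acc_label = if (sensor == "accelerometer") lab else NA_character_,
                      mag_label = if (sensor == "magnetometer") lab else NA_character_,
                      fused_label = lab, paired = FALSE, stringsAsFactors = FALSE)
    return(out[order(out$t), , drop = FALSE])
  }

  acc_trace <- acc_trace[order(acc_trace$t), , drop = FALSE]
  mag_trace <- mag_trace[order(mag_trace$t), , drop = FALSE]
  if (is.null(pairing_tol)) pairing_tol <- default_pairing_tol(acc_trace$t)
  acc_lab <- classify_point(trace_mat(acc_trace), model, "accelerometer", mode)
  mag_lab <- classify_point(trace_mat(mag_trace), model, "magnetometer", mode)

  idx <- nearest_index(acc_trace$t, mag_trace$t)
  paired <- abs(mag_trace$t[idx] - acc_trace$t) <= pairing_tol
  recs <- data.frame(t = acc_trace$t,
                     acc_label = acc_lab,
                     mag_label = ifelse(paired, mag_lab[idx], NA_character_),
                     paired = paired, stringsAsFactors = FALSE)
  # magnetometer samples never chosen as a partner and beyond tolerance of
  # every accelerometer timestamp become their own single-sensor records
  ridx <- nearest_index(mag_trace$t, acc_trace$t)
  orphan <- abs(acc_trace$t[ridx] - mag_trace$t) > pairing_tol
  if (any(orphan)) {
    recs <- rbind(recs, data.frame(t = mag_trace$t[orphan],
                                   acc_label = NA_character_,
                                   mag_label = mag_lab[orphan],
                                   paired = FALSE, stringsAsFactors = FALSE))
  }
  recs$fused_label <- fuse_labels(recs$acc_label, recs$mag_label)
  recs <- recs[order(recs$t), c("t", "acc_label", "mag_label", "fused_label", "paired")]
  rownames(recs) <- NULL
  recs
}

#' Score a monitoring session
#'
#' The session score is the percentage of classification records inside the
#' scoring window whose fused label is `"correct"` — the figure of merit a
#' wearer reviews after a monitoring period of up to 24 hours. Every record
#' is weighted equally (uniform sampling assumed).
#'
#' @param records data frame from [classify_stream()] (needs `t` and
#'   `fused_label`).
#' @param window length-2 numeric `c(start, end)` in seconds; defaults to the
#'   full record span.
#' @return object of class `session_score`: list with `window_start`,
#'   `window_end`, `n_records`, `score_percent`.
#' @export
score_session <- function(records, window = NULL) {
  if (is.null(window)) window <- range(records$t)
  if (length(window) != 2L || !is.numeric(window) || window[2] < window[1]) {
    pw_error("pw_invalid_parameter", "window must be numeric c(start, end) with end >= start")
  }
  keep <- records$t >= window[1] & records$t <= window[2]
  if (!any(keep)) {
    pw_error("pw_undefined_score", "no classification records fall inside the scoring window")
  }
  fused <- check_labels(records$fused_label[keep], "fused labels")
  structure(list(window_start = window[1], window_end = window[2],
                 n_records = sum(keep),
                 score_percent = 100 * mean(fused == "correct")),
            class = "session_score")
}

#' @export
print.session_score <- function(x, ...) {
  cat(sprintf("<session_score> %.1f%% correct over [%g, %g] s (%d records)\n",
              x$score_percent, x$window_start, x$window_end, x$n_records))
  invisible(x)
}

#' Classification accuracy against ground truth
#'
#' Accuracy is the percentage of time steps at which the predicted posture
#' label matches the reference label.
#'
#' @param predicted,truth equal-length character vectors of
#'   `"correct"`/`"incorrect"`.
#' @return percentage in \[0, 100\].
#' @export
classification_accuracy <- function(predicted, truth) {
  predicted <- check_labels(predicted, "predicted labels")
  truth <- check_labels(truth, "truth labels")
  if (length(predicted) != length(truth) || length(predicted) == 0L) {
    pw_error("pw_invalid_data", "predicted and truth labels must have equal positive length")
  }
  100 * mean(predicted == truth)
}
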
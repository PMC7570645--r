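#' Write sensor traces to a delimited trace file
#'
#' The trace format is comma-delimited text with `#`-prefixed metadata lines
#' (units per sensor and, optionally, the sample rate), a header row and one
#' row per sample: `t,sensor,x,y,z` plus optional `truth` and `pose` columns
#' (per-sample ground-truth label; calibration pose tag). Numbers are written
#' with 17 significant digits so a write/read round trip is lossless.
#'
#' @param traces named list of data frames (`t`, `x`, `y`, `z`) keyed by
#'   sensor name.
#' @param path output file path.
#' @param units named list of unit strings per sensor.
#' @param sample_rate optional nominal sampling rate (Hz), recorded as
#'   metadata.
#' @param truth optional named list of per-sample label vectors per sensor.
#' @param pose optional named list of per-sample pose tags per sensor.
#' @return `path`, invisibly.
#' @export
write_trace <- function(traces, path,
                        units = list(accelerometer = "m/s2", magnetometer = "uT"),
                        sample_rate = NULL, truth = NULL, pose = NULL) {
  for (s in names(traces)) check_sensor(s)
  has_truth <- !is.null(truth)
  has_pose <- !is.null(pose)
  lines <- c("# posturewatch trace v1",
             paste0("# units: ", paste(sprintf("%s=%s", names(traces),
                                               unlist(units[names(traces)])),
                                       collapse = " ")))
  if (!is.null(sample_rate)) lines <- c(lines, paste0("# sample_rate: ", sample_rate))
  header <- c("t", "sensor", "x", "y", "z",
              if (has_truth) "truth", if (has_pose) "pose")
  lines <- c(lines, paste(header, collapse = ","))
  for (s in names(traces)) {
    tr <- traces[[s]]
    row <- paste(fmt_num(tr$t), s, fmt_num(tr$x), fmt_num(tr$y), fmt_num(tr$z), sep = ",")
    if (has_truth) row <- paste(row, truth[[s]] %||% rep("", nrow(tr)), sep = ",")
    if (has_pose) row <- paste(row, pose[[s]] %||% rep("", nrow(tr)), sep = ",")
    lines <- c(lines, row)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sensor trace file
#'
#' Parses the trace format of [write_trace()]. Malformed rows (wrong field
#' count, non-numeric values, unknown sensor names) raise a parse error
#' naming the offending line number; timestamps must be non-decreasing within
#' each sensor.
#'
#' @param path trace file path.
#' @return list with `traces` (named list of data frames `t,x,y,z` per
#'   sensor, with `truth`/`pose` columns when present in the file), `units`
#'   (named list) and `sample_rate` (or `NULL`).
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) pw_error("pw_io_error", sprintf("trace file not found: %s", path))
  lines <- readLines(path)
  meta <- grepl("^#", lines)
  units <- list()
  sample_rate <- NULL
  for (ml in lines[meta]) {
    if (grepl("^# units:", ml)) {
      for (tok in strsplit(sub("^# units:\\s*", "", ml), "\\s+")[[1]]) {
        kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
        if (length(kv) == 2L) units[[kv[1]]] <- kv[2]
      }
    } else if (grepl("^# sample_rate:", ml)) {
      sample_rate <- as.numeric(sub("^# sample_rate:\\s*", "", ml))
    }
  }
  body_idx <- which(!meta)
  if (length(body_idx) < 2L) pw_error("pw_parse_error", "trace file has no data rows")
  header <- strsplit(lines[body_idx[1]], ",", fixed = TRUE)[[1]]
  required <- c("t", "sensor", "x", "y", "z")
  if (!all(required %in% header)) {
    pw_error("pw_parse_error",
             sprintf("trace header must contain columns %s; got '%s'",
                     paste(required, collapse = ","), lines[body_idx[1]]))
  }
  rows_idx <- body_idx[-1]
  fields <- strsplit(lines[rows_idx], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- rows_idx[which(nf != length(header))[1]]
    pw_error("pw_parse_error", sprintf("line %d: expected %d fields, found %d",
                                       bad, length(header), nf[which(nf != length(header))[1]]))
  }
  m <- do.call(rbind, fields)
  colnames(m) <- header
  num <- c("t", "x", "y", "z")
  vals <- suppressWarnings(apply(m[, num, drop = FALSE], 2L, as.numeric))
  vals <- matrix(vals, ncol = length(num), dimnames = list(NULL, num))
  if (any(is.na(vals))) {
    bad <- rows_idx[which(rowSums(is.na(vals)) > 0)[1]]
    pw_error("pw_parse_error", sprintf("line %d: non-numeric value in a numeric column", bad))
  }
  sensors <- m[, "sensor"]
  if (any(!sensors %in% SENSORS)) {
    bad <- rows_idx[which(!sensors %in% SENSORS)[1]]
    pw_error("pw_parse_error", sprintf("line %d: unknown sensor name '%s'",
                                       bad, sensors[which(!sensors %in% SENSORS)[1]]))
  }
  traces <- list()
  for (s in unique(sensors)) {
    sel <- sensors == s
    df <- data.frame(t = vals[sel, "t"], x = vals[sel, "x"],
                     y = vals[sel, "y"], z = vals[sel, "z"])
    if ("truth" %in% header) df$truth <- m[sel, "truth"]
    if ("pose" %in% header) df$pose <- m[sel, "pose"]
    if (is.unsorted(df$t)) {
      pw_error("pw_parse_error",
               sprintf("timestamps for sensor '%s' are not non-decreasing", s))
    }
    traces[[s]] <- df
  }
  list(traces = traces, units = units, sample_rate = sample_rate)
}

#' Serialize a calibration model to JSON
#'
#' Writes every region's mean, row-major covariance, confidence level,
#' density threshold, pose label, sensor and ridge flag, plus the model-level
#' confidence and units, at full float precision. [read_calibration()] is the
#' lossless inverse (eigenstructure and offsets are recomputed from the
#' stored covariance).
#'
#' @param model a `calibration_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  regions <- lapply(unname(model$regions), function(r) {
    list(pose_label = r$pose_label, sensor = r$sensor, conf = r$conf,
         mu = r$mu, sigma = as.numeric(t(r$sigma)), tau = r$tau,
         ridged = r$ridged)
  })
  jsonlite::write_json(list(format = "posturewatch_calibration_v1",
                            conf = model$conf, units = model$units,
                            regions = regions),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path JSON file written by [write_calibration()].
#' @return a `calibration_model`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) pw_error("pw_io_error", sprintf("model file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(doc$format, "posturewatch_calibration_v1")) {
    pw_error("pw_parse_error", "not a posturewatch calibration model file")
  }
  regions <- list()
  for (r in doc$regions) {
    sigma <- matrix(as.numeric(r$sigma), 3L, 3L, byrow = TRUE)
    off <- confidence_offsets(sigma, r$conf)
    reg <- structure(list(mu = as.numeric(r$mu), sigma = sigma, conf = r$conf,
                          tau = r$tau, eigvals = off$eigvals,
                          eigvecs = off$eigvecs, delta = off$delta,
                          pose_label = r$pose_label, sensor = r$sensor,
                          ridged = isTRUE(r$ridged)),
                     class = "gaussian_region")
    regions[[paste(r$sensor, r$pose_label, sep = ":")]] <- reg
  }
  structure(list(regions = regions, conf = doc$conf, units = doc$units),
            class = "calibration_model")
}

#' Write classification records to delimited text
#'
#' Columns `t,acc_label,mag_label,fused_label,paired`; labels serialized as
#' lowercase `"correct"`/`"incorrect"`, missing verdicts as empty fields.
#'
#' @param records data frame from [classify_stream()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  out$t <- fmt_num(out$t)
  out[is.na(out)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read classification records written by [write_records()]
#' @param path records CSV path.
#' @return data frame with columns `t`, `acc_label`, `mag_label`,
#'   `fused_label`, `paired`.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) pw_error("pw_io_error", sprintf("records file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(t = "numeric", acc_label = "character",
                                       mag_label = "character",
                                       fused_label = "character",
                                       paired = "logical"))
  for (col in c("acc_label", "mag_label", "fused_label")) {
    df[[col]][df[[col]] == ""] <- NA_character_
    check_labels(df[[col]], col)
  }
  df
}

#' Write a session-score report as JSON
#' @param score a `session_score` from [score_session()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(score, path) {
  stopifnot(inherits(score, "session_score"))
  jsonlite::write_json(unclass(score), path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Write / read an angle trace as two-column delimited text
#'
#' @param trace data frame with columns `t` and `angle` (degrees).
#' @param path file path.
#' @return `path` (write) or the angle trace data frame (read).
#' @export
write_angle_trace <- function(trace, path) {
  writeLines(c("t,angle_deg",
               paste(fmt_num(trace$t), fmt_num(trace$angle), sep = ",")), path)
  invisible(path)
}

#' @rdname write_angle_trace
#' @export
read_angle_trace <- function(path) {
  if (!file.exists(path)) pw_error("pw_io_error", sprintf("angle file not found: %s", path))
  df <- utils::read.csv(path, colClasses = "numeric")
  data.frame(t = df$t, angle = df$angle_deg)
}

#' Read a scenario definition file
#'
#' Scenario files are YAML or JSON (by extension) with fields `sample_rate`,
#' `seed` and a list `segments` of
#' `{duration_s, back_tilt_deg, back_straight, shoulder_state, arm_pose,
#' stance, truth}`; omitted state fields default to the upright
#' standing/arms-down state.
#'
#' @param path scenario file (`.yaml`/`.yml` or `.json`).
#' @return a [posture_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) pw_error("pw_io_error", sprintf("scenario file not found: %s", path))
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (is.null(doc$segments)) pw_error("pw_parse_error", "scenario file has no 'segments'")
  segments <- lapply(doc$segments, function(sg) {
    list(duration = sg$duration_s,
         state = wearer_state(back_tilt = sg$back_tilt_deg %||% 0,
                              back_straight = sg$back_straight %||% TRUE,
                              shoulder_state = sg$shoulder_state %||% 0,
                              arm_pose = sg$arm_pose %||% "arms_down",
                              stance = sg$stance %||% "standing"),
         truth = sg$truth %||% "correct")
  })
  posture_scenario(segments, sample_rate = doc$sample_rate %||% 10,
                   seed = doc$seed %||% 1)
}
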
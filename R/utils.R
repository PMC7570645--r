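# Internal helpers shared across modules.

SENSORS <- c("accelerometer", "magnetometer")
ARM_POSES <- c("arms_down", "right_up", "left_up", "arms_up")
STANCES <- c("standing", "sitting")
LABELS <- c("correct", "incorrect")

pw_error <- function(subclass, msg) {
  stop(errorCondition(msg, class = c(subclass, "posturewatch_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce samples to an n x 3 numeric matrix; reject non-finite values.
as_samples <- function(x, what = "samples") {
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) x <- matrix(x, 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) {
    pw_error("pw_invalid_data", sprintf("%s must have 3 columns, got %d", what, ncol(x)))
  }
  if (!all(is.finite(x))) {
    pw_error("pw_invalid_data", sprintf("%s contain non-finite values", what))
  }
  x
}

check_sensor <- function(sensor) {
  if (length(sensor) != 1L || !sensor %in% SENSORS) {
    pw_error("pw_invalid_parameter",
             sprintf("unknown sensor '%s' (expected one of: %s)",
                     paste(sensor, collapse = ","), paste(SENSORS, collapse = ", ")))
  }
  sensor
}

check_labels <- function(x, what = "labels") {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% LABELS
  if (any(bad)) {
    pw_error("pw_invalid_data",
             sprintf("%s must be 'correct' or 'incorrect'; got '%s'", what, x[which(bad)[1L]]))
  }
  x
}

# Rotation about the lateral (x) axis by `deg` degrees; used for back pitch.
rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), sin(th),
           0, -sin(th), cos(th)), 3L, 3L)
}

# Rotation about the sagittal (y) axis; used for lateral lean (roll).
rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, -sin(th),
           0, 1, 0,
           sin(th), 0, cos(th)), 3L, 3L)
}

vec_norm <- function(v) sqrt(sum(v^2))

# Default pairing tolerance: half the median sampling period of a trace.
default_pairing_tol <- function(t) {
  if (length(t) < 2L) return(Inf)
  stats::median(diff(sort(t))) / 2
}

fmt_num <- function(x) sprintf("%.17g", x)
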
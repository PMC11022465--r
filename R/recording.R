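#' Construct a raw IMU recording
#'
#' Container for one measurement with one or more body-worn sensors. Each
#' sensor stream holds sample times (seconds), tri-axial acceleration
#' (m/s^2, columns x = anterior, y = left, z = up at calibration posture)
#' and, optionally, tri-axial angular rate (rad/s).
#'
#' @param sensors named list; names are placements from
#'   `{left_foot, right_foot, low_back, calf}`, each element a list with
#'   `time` (numeric, strictly increasing), `acc` (n x 3 matrix) and
#'   optionally `gyr` (n x 3 matrix or `NULL`).
#' @param rate nominal sampling rate in Hz (> 0).
#' @param meta named list of free-form metadata (units, configured ranges,
#'   start timestamp, truth records, ...).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(sensors, rate, meta = list()) {
  placements <- c("left_foot", "right_foot", "low_back", "calf")
  if (length(sensors) == 0L || is.null(names(sensors)) ||
      !all(names(sensors) %in% placements)) {
    stop("sensors must be a named list with placements in {",
         paste(placements, collapse = ", "), "}", call. = FALSE)
  }
  if (!is.numeric(rate) || rate <= 0) {
    stop("nominal rate must be > 0", call. = FALSE)
  }
  spans <- sapply(sensors, function(s) range(s$time))
  for (nm in names(sensors)) {
    s <- sensors[[nm]]
    if (any(diff(s$time) <= 0)) {
      stop("sample times must be strictly increasing (", nm, ")",
           call. = FALSE)
    }
    if (!is.matrix(s$acc) || ncol(s$acc) != 3 ||
        nrow(s$acc) != length(s$time)) {
      stop("acc must be an n x 3 matrix matching time (", nm, ")",
           call. = FALSE)
    }
    if (anyNA(s$acc) || anyNA(s$time) ||
        (!is.null(s$gyr) && anyNA(s$gyr))) {
      stop("recording contains NaN/NA (", nm, ")", call. = FALSE)
    }
    if (!is.null(s$gyr) &&
        (!is.matrix(s$gyr) || ncol(s$gyr) != 3 ||
         nrow(s$gyr) != length(s$time))) {
      stop("gyr must be NULL or an n x 3 matrix matching time (", nm, ")",
           call. = FALSE)
    }
  }
  tol <- 1 / rate + 1e-9
  if (length(sensors) > 1 &&
      (diff(range(spans[1, ])) > tol || diff(range(spans[2, ])) > tol)) {
    stop("sensor streams must cover the same interval within one sample",
         call. = FALSE)
  }
  structure(list(sensors = sensors, rate = rate, meta = meta),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d sensor(s) @ %g Hz nominal\n",
              length(x$sensors), x$rate))
  for (nm in names(x$sensors)) {
    s <- x$sensors[[nm]]
    cat(sprintf("  %-10s %7d samples, %.1f s, gyro: %s\n", nm,
                length(s$time), diff(range(s$time)),
                if (is.null(s$gyr)) "no" else "yes"))
  }
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an `imu_recording`.
#' @return Duration of the first sensor stream in seconds.
#' @export
recording_duration <- function(recording) {
  t <- recording$sensors[[1]]$time
  diff(range(t)) + 1 / recording$rate
}

#' Write / read a recording as plain tabular text
#'
#' One whitespace-separated file per sensor (`<placement>.txt` with columns
#' `timestamp_s ax ay az gx gy gz`; gyro columns `NA` when absent) plus a
#' `meta.yaml` sidecar with placement list, nominal rate and units.
#'
#' @param recording an `imu_recording`.
#' @param dir directory to write into (created if missing).
#' @return `write_recording` returns `dir` invisibly; `read_recording`
#'   returns the reconstructed `imu_recording`.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(recording$sensors)) {
    s <- recording$sensors[[nm]]
    g <- if (is.null(s$gyr)) matrix(NA_real_, nrow(s$acc), 3) else s$gyr
    df <- data.frame(timestamp_s = s$time,
                     ax = s$acc[, 1], ay = s$acc[, 2], az = s$acc[, 3],
                     gx = g[, 1], gy = g[, 2], gz = g[, 3])
    write.table(df, file.path(dir, paste0(nm, ".txt")), row.names = FALSE,
                quote = FALSE)
  }
  meta <- recording$meta
  meta$placements <- names(recording$sensors)
  meta$rate_hz <- recording$rate
  meta$units <- list(acc = "m/s^2", gyr = "rad/s", time = "s")
  # keep the sidecar plain: drop non-scalar truth payloads
  meta <- meta[vapply(meta, function(x)
    is.atomic(x) || is.list(x) && all(vapply(x, is.atomic, TRUE)), TRUE)]
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  sensors <- list()
  for (nm in meta$placements) {
    df <- read.table(file.path(dir, paste0(nm, ".txt")), header = TRUE)
    gyr <- as.matrix(df[, c("gx", "gy", "gz")])
    if (anyNA(gyr)) gyr <- NULL
    sensors[[nm]] <- list(time = df$timestamp_s,
                          acc = unname(as.matrix(df[, c("ax", "ay", "az")])),
                          gyr = if (is.null(gyr)) NULL else unname(gyr))
  }
  rate <- meta$rate_hz
  meta$placements <- NULL
  meta$rate_hz <- NULL
  imu_recording(sensors, rate, meta)
}
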
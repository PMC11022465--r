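#' Preprocess a raw IMU recording
#'
#' Resamples every sensor stream onto a uniform grid (linear interpolation)
#' and removes the per-axis gyroscope offset. The offset is the median
#' angular rate over detected stationary samples (acceleration norm within
#' 0.3 m/s^2 of gravity for at least 0.2 s); when fewer than half a second
#' of stationary data exists the whole-recording median is used instead.
#' Acceleration is unchanged apart from resampling.
#'
#' @param recording an [imu_recording()].
#' @param target_rate output sampling rate in Hz (default 100).
#' @return A preprocessed [imu_recording()] at `target_rate`; metadata gains
#'   `gyro_offset` (per sensor) and `preprocessed = TRUE`.
#' @export
preprocess <- function(recording, target_rate = 100) {
  stopifnot(inherits(recording, "imu_recording"))
  span <- range(recording$sensors[[1]]$time)
  if (diff(span) < 2) {
    stop("too short: need >= 2 s of data", call. = FALSE)
  }
  t0 <- max(sapply(recording$sensors, function(s) min(s$time)))
  t1 <- min(sapply(recording$sensors, function(s) max(s$time)))
  grid <- seq(t0, t1, by = 1 / target_rate)
  offsets <- list()
  sensors <- lapply(recording$sensors, function(s) {
    acc <- apply(s$acc, 2, function(col) approx(s$time, col, grid)$y)
    gyr <- NULL
    if (!is.null(s$gyr)) {
      gyr <- apply(s$gyr, 2, function(col) approx(s$time, col, grid)$y)
      nrm <- sqrt(rowSums(acc^2))
      still <- moving_average(abs(nrm - GRAVITY), 0.2 * target_rate) < 0.3
      off <- if (sum(still) >= 0.5 * target_rate) {
        apply(gyr[still, , drop = FALSE], 2, median)
      } else {
        apply(gyr, 2, median)
      }
      gyr <- sweep(gyr, 2, off)
    } else {
      off <- rep(NA_real_, 3)
    }
    list(time = grid, acc = acc, gyr = gyr, offset = off)
  })
  for (nm in names(sensors)) offsets[[nm]] <- sensors[[nm]]$offset
  sensors <- lapply(sensors, function(s) s[c("time", "acc", "gyr")])
  meta <- recording$meta
  meta$preprocessed <- TRUE
  meta$gyro_offset <- offsets
  imu_recording(sensors, target_rate, meta)
}
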
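# Synthetic multi-hour single-sensor (calf) recording driven by an activity
# timeline. Gait bouts use the same swing waveform model as the 2MWT
# generator (AP full-sine lobe whose double integral is the stride length;
# vertical = gravity plus a small step-frequency sinusoid). Sedentary and
# standing bouts are gravity plus postural sway; off-body bouts are
# gravity with near-zero variance.

.daily_gait_bout <- function(t_local, truth, stance_fraction, seed) {
  n <- length(t_local)
  duration <- n * (t_local[2] - t_local[1])
  st <- .stride_times(duration, truth$stride_time, truth$stride_time_cv,
                      child_seed(seed, "strides"))
  starts <- cumsum(c(0, st[-length(st)]))
  ax <- numeric(n)
  for (k in seq_along(st)) {
    Ts <- (1 - stance_fraction) * st[k]
    sw0 <- starts[k] + stance_fraction * st[k]
    A <- 2 * pi * truth$gait_speed * st[k] / Ts^2
    ax <- ax + .full_sine_lobe(t_local, sw0, Ts, A)
  }
  az <- GRAVITY + 0.5 * sin(2 * pi * t_local * 2 / truth$stride_time)
  list(ax = ax, ay = numeric(n), az = az)
}

.daily_quiet_bout <- function(t_local, kind, seed) {
  n <- length(t_local)
  sway_amp <- switch(kind, sedentary = 0.3, standing = 0.15, off_body = 0)
  with_seed(seed, {
    f <- runif(1, 0.1, 0.3)
    ph <- runif(1, 0, 2 * pi)
    list(ax = sway_amp * sin(2 * pi * f * t_local + ph),
         ay = sway_amp * 0.5 * cos(2 * pi * f * t_local + ph),
         az = rep(GRAVITY, n))
  })
}

#' Generate a synthetic daily-life calf recording
#'
#' Renders an [activity_timeline()] into a single-sensor acceleration-only
#' recording (the daily-wear configuration) plus the exact day truth: total
#' step count, per-bout true gait speeds and true wear time. Steps per gait
#' bout are `floor(duration / step_time)` with step time half the stride
#' time.
#'
#' @param timeline an [activity_timeline()].
#' @param rate sampling rate in Hz (default 52).
#' @param noise_sd white-noise SD in m/s^2 added during worn bouts
#'   (off-body noise is 0.002 m/s^2 regardless).
#' @param stance_fraction stance fraction of gait bouts.
#' @param start_time_s clock time of the first sample, seconds after
#'   midnight (day boundaries fall at multiples of 86400 s).
#' @param include_gyro also synthesize a matching angular-rate stream
#'   (sagittal swing lobe during gait); the study wear configuration is
#'   acceleration-only, so the default is `FALSE`.
#' @param seed integer seed.
#' @return A list with `recording` (an [imu_recording()], placement
#'   `calf`) and `day_truth` (`steps`, `bout_speeds`, `wear_time_s`,
#'   `labels` = per-bout labels, `bout_starts`).
#' @export
#' @examples
#' tl <- activity_timeline("gait", 60, list(gait_truth(gait_speed = 1)))
#' d <- generate_daily_recording(tl, seed = 2)
#' d$day_truth$steps
generate_daily_recording <- function(timeline, rate = 52, noise_sd = 0.3,
                                     stance_fraction = 0.45,
                                     start_time_s = 8 * 3600,
                                     include_gyro = FALSE, seed = 1) {
  if (!inherits(timeline, "activity_timeline")) {
    stop("timeline must be an activity_timeline", call. = FALSE)
  }
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  total <- attr(timeline, "total_duration")
  n <- floor(total * rate)
  t <- (seq_len(n) - 1) / rate
  ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
  gy <- if (include_gyro) numeric(n) else NULL
  bout_ends <- cumsum(timeline$durations)
  bout_starts <- c(0, bout_ends[-length(bout_ends)])
  steps <- 0L
  bout_speeds <- numeric(0)
  for (i in seq_along(timeline$labels)) {
    idx <- which(t >= bout_starts[i] & t < bout_ends[i])
    if (!length(idx)) next
    t_loc <- t[idx] - bout_starts[i]
    lab <- timeline$labels[i]
    bseed <- child_seed(seed, paste0("bout", i))
    if (lab == "gait") {
      tr <- timeline$truths[[i]]
      sig <- .daily_gait_bout(t_loc, tr, stance_fraction, bseed)
      steps <- steps + floor(timeline$durations[i] / (tr$stride_time / 2))
      bout_speeds <- c(bout_speeds, tr$gait_speed)
      if (include_gyro) {
        st <- .stride_times(timeline$durations[i], tr$stride_time,
                            tr$stride_time_cv, child_seed(bseed, "strides"))
        starts <- cumsum(c(0, st[-length(st)]))
        g <- numeric(length(idx))
        for (k in seq_along(st)) {
          Ts <- (1 - stance_fraction) * st[k]
          g <- g + .swing_lobe(t_loc, starts[k] + stance_fraction * st[k],
                               Ts, pi * tr$gait_speed * st[k] / Ts)
        }
        gy[idx] <- g
      }
    } else {
      sig <- .daily_quiet_bout(t_loc, lab, bseed)
    }
    nsd <- if (lab == "off_body") 0.002 else noise_sd
    noise <- with_seed(child_seed(bseed, "noise"),
                       matrix(rnorm(3 * length(idx), 0, nsd), ncol = 3))
    ax[idx] <- sig$ax + noise[, 1]
    ay[idx] <- sig$ay + noise[, 2]
    az[idx] <- sig$az + noise[, 3]
  }
  gyr <- if (include_gyro) {
    cbind(numeric(n), gy, numeric(n))
  } else NULL
  rec <- imu_recording(
    list(calf = list(time = t, acc = unname(cbind(ax, ay, az)),
                     gyr = gyr)),
    rate,
    meta = list(protocol = "daily_life", start_time_s = start_time_s))
  wear <- sum(timeline$durations[timeline$labels != "off_body"])
  list(recording = rec,
       day_truth = list(steps = steps, bout_speeds = bout_speeds,
                        wear_time_s = wear, labels = timeline$labels,
                        bout_starts = bout_starts,
                        bout_durations = timeline$durations))
}
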
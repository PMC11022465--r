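# Synthetic two-minute-walk-test signals: three sensors (left/right foot,
# low back) with exact ground-truth gait events. Waveform model: foot
# sagittal angular rate = stance plateau + half-sine swing peak (magnitude
# scaled to stride length) with small negative dips at toe-off and initial
# contact; trunk acceleration = step- and stride-frequency sinusoids plus
# gravity; additive white Gaussian noise.

# per-foot stride schedule; returns stride start times (= previous ICs)
.stride_times <- function(duration, stride_time, cv, seed) {
  with_seed(seed, {
    n_max <- ceiling(duration / stride_time * 2) + 4
    mult <- pmax(0.5, 1 + cv * rnorm(n_max))
    st <- stride_time * mult
    keep <- cumsum(st) < duration + 2 * stride_time
    st[keep]
  })
}

.swing_lobe <- function(t, sw0, Ts, A) {
  idx <- t >= sw0 & t < sw0 + Ts
  out <- numeric(length(t))
  out[idx] <- A * sin(pi * (t[idx] - sw0) / Ts)
  out
}

# full sine over the swing: accelerate then decelerate, net velocity zero,
# displacement A * Ts^2 / (2 * pi)
.full_sine_lobe <- function(t, sw0, Ts, A) {
  idx <- t >= sw0 & t < sw0 + Ts
  out <- numeric(length(t))
  out[idx] <- A * sin(2 * pi * (t[idx] - sw0) / Ts)
  out
}

.dip <- function(t, center, width = 0.12, amp = 1) {
  idx <- t >= center - width / 2 & t < center + width / 2
  out <- numeric(length(t))
  out[idx] <- -amp * sin(pi * (t[idx] - (center - width / 2)) / width)
  out
}

# one foot's gyro/acc streams given its swing windows
.foot_stream <- function(t, swings, stride_lens, noise_sd, seed) {
  gy <- numeric(length(t))
  ax <- numeric(length(t))
  az <- rep(GRAVITY, length(t))
  for (k in seq_len(nrow(swings))) {
    sw0 <- swings[k, 1]
    Ts <- swings[k, 2] - swings[k, 1]
    L <- stride_lens[k]
    gy <- gy + .swing_lobe(t, sw0, Ts, pi * L / Ts) +
      .dip(t, sw0 - 0.08) + .dip(t, sw0 + Ts + 0.08)
    ax <- ax + .full_sine_lobe(t, sw0, Ts, 2 * pi * L / Ts^2)
  }
  with_seed(seed, {
    n <- length(t)
    list(acc = cbind(ax + rnorm(n, 0, noise_sd),
                     rnorm(n, 0, noise_sd),
                     az + rnorm(n, 0, noise_sd)),
         gyr = cbind(rnorm(n, 0, noise_sd * 0.3),
                     gy + rnorm(n, 0, noise_sd * 0.3),
                     rnorm(n, 0, noise_sd * 0.3)))
  })
}

#' Generate a synthetic instrumented 2MWT recording
#'
#' Emulates a two-minute walk at self-selected speed with IMUs on both feet
#' and the low back, returning the recording together with the exact
#' ground-truth gait events it encodes (initial and final contacts per
#' foot). With `asymmetry_ratio > 1` the two step times differ by that
#' ratio. Identical seeds give bit-identical output.
#'
#' @param truth a [gait_truth()].
#' @param duration recording length in seconds (> 0; default 120).
#' @param rate sampling rate in Hz (> 0; default 104).
#' @param noise_sd additive white-noise SD on acceleration in m/s^2
#'   (gyroscope noise is 0.3 x this value, in rad/s).
#' @param stance_fraction fraction of the stride spent in stance.
#' @param gyro_bias optional constant per-axis gyroscope offset (length-3,
#'   rad/s) added to every sensor, for testing offset correction.
#' @param seed integer seed.
#' @return A list with `recording` (an [imu_recording()]) and `events`
#'   (per foot: `ic`, `fc`, vectors of seconds).
#' @export
#' @examples
#' g <- generate_2mwt_signals(gait_truth(stride_time = 1.2), duration = 30,
#'                            seed = 7)
#' range(diff(g$events$left_foot$ic))
generate_2mwt_signals <- function(truth, duration = 120, rate = 104,
                                  noise_sd = 0.1, stance_fraction = 0.6,
                                  gyro_bias = c(0, 0, 0), seed = 1) {
  stopifnot(inherits(truth, "gait_truth"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be > 0", call. = FALSE)
  }
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  n <- floor(duration * rate)
  t <- (seq_len(n) - 1) / rate

  st_l <- .stride_times(duration, truth$stride_time, truth$stride_time_cv,
                        child_seed(seed, "strides_left"))
  # right foot shares the stride schedule, phase-shifted by the left step
  r <- truth$asymmetry_ratio
  step_l_frac <- r / (1 + r)  # left-to-right step as fraction of stride

  build_events <- function(starts, strides) {
    ic <- starts + strides            # IC at stride end (= swing end)
    fc <- starts + stance_fraction * strides  # toe-off
    keep <- ic < duration
    list(ic = ic[keep], fc = fc[keep],
         starts = starts[keep], strides = strides[keep])
  }
  starts_l <- cumsum(c(0, st_l[-length(st_l)]))
  ev_l <- build_events(starts_l, st_l)
  # right initial contacts sit at a fixed fraction (the left step) between
  # consecutive left contacts, so both feet share the same cycle timing
  grid_l <- c(0, cumsum(st_l))
  grid_r <- grid_l[-length(grid_l)] + step_l_frac * diff(grid_l)
  ev_r <- build_events(grid_r[-length(grid_r)], diff(grid_r))

  swings <- function(ev) cbind(ev$starts + stance_fraction * ev$strides,
                               ev$ic)
  lens <- function(ev) truth$gait_speed * ev$strides

  left <- .foot_stream(t, swings(ev_l), lens(ev_l), noise_sd,
                       child_seed(seed, "left_foot"))
  right <- .foot_stream(t, swings(ev_r), lens(ev_r), noise_sd,
                        child_seed(seed, "right_foot"))

  # trunk: stride phase from the left-foot schedule
  knots <- c(starts_l, starts_l[length(starts_l)] + st_l[length(st_l)])
  phase <- approx(knots, 2 * pi * (seq_along(knots) - 1), xout = t,
                  rule = 2)$y
  asym <- r - 1
  v_sig <- 1.2 * sin(2 * phase) + 0.8 * asym * sin(phase)
  ap_sig <- 0.9 * sin(2 * phase + 0.3) + (0.25 + 0.8 * asym) * sin(phase + 0.2)
  ml_sig <- 0.8 * sin(phase) + 0.15 * sin(2 * phase)
  trunk <- with_seed(child_seed(seed, "low_back"), {
    list(acc = cbind(ap_sig + rnorm(n, 0, noise_sd),
                     ml_sig + rnorm(n, 0, noise_sd),
                     GRAVITY + v_sig + rnorm(n, 0, noise_sd)),
         gyr = cbind(rnorm(n, 0, noise_sd * 0.3),
                     rnorm(n, 0, noise_sd * 0.3),
                     rnorm(n, 0, noise_sd * 0.3)))
  })

  add_bias <- function(s) {
    s$gyr <- sweep(s$gyr, 2, gyro_bias, "+")
    s
  }
  sensors <- list(
    left_foot = add_bias(list(time = t, acc = left$acc, gyr = left$gyr)),
    right_foot = add_bias(list(time = t, acc = right$acc, gyr = right$gyr)),
    low_back = add_bias(list(time = t, acc = trunk$acc, gyr = trunk$gyr)))
  rec <- imu_recording(sensors, rate,
                       meta = list(protocol = "2mwt", path_length_m = 14,
                                   acc_range = "8g (configured)",
                                   gyro_range = "500 deg/s",
                                   distance_m = truth$gait_speed * duration))
  events <- list(left_foot = list(ic = ev_l$ic, fc = ev_l$fc),
                 right_foot = list(ic = ev_r$ic, fc = ev_r$fc))
  list(recording = rec, events = events, truth = truth)
}
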
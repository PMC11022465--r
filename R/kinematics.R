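# Gravity removal, ZUPT stance/swing segmentation and double integration:
# the chain that turns a gait epoch into a speed estimate.

# core gravity-free computation on raw arrays; returns linear acceleration
# in the sensor frame plus the principal horizontal (AP) component
.linear_core <- function(acc, gyr, rate, gain = 0.02) {
  n <- nrow(acc)
  if (is.null(gyr)) {
    grav <- apply(acc, 2, lowpass_filter, rate = rate, cutoff = 0.25)
  } else {
    # complementary attitude filter: rotate the gravity estimate by the
    # measured angular rate, nudge it toward the accelerometer low-pass
    grav <- matrix(0, n, 3)
    g <- acc[1, ]
    g <- g / sqrt(sum(g^2)) * GRAVITY
    dt <- 1 / rate
    for (i in seq_len(n)) {
      if (i > 1) {
        w <- gyr[i, ]
        g <- g - dt * c(w[2] * g[3] - w[3] * g[2],
                        w[3] * g[1] - w[1] * g[3],
                        w[1] * g[2] - w[2] * g[1])
      }
      g <- (1 - gain) * g + gain * acc[i, ]
      g <- g / sqrt(sum(g^2)) * GRAVITY
      grav[i, ] <- g
    }
  }
  lin <- acc - grav
  # ground-referenced horizontal plane: project out the (mean) gravity
  # direction, then take the first principal component as AP
  gbar <- colMeans(grav)
  gbar <- gbar / sqrt(sum(gbar^2))
  horiz <- lin - outer(as.numeric(lin %*% gbar), gbar)
  cv <- cov(horiz)
  ap_dir <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  list(linear = lin, ap = as.numeric(horiz %*% ap_dir), ap_dir = ap_dir,
       gravity = grav)
}

#' Gravity-free linear acceleration of a gait epoch
#'
#' When angular rate is available, orientation is tracked with a
#' complementary attitude filter (the accelerometer low-frequency content
#' corrects gyroscope drift with a configurable gain); in the
#' acceleration-only wear configuration gravity is estimated by per-epoch
#' low-pass filtering (0.25 Hz) and subtracted. The anterior-posterior
#' (AP) axis is the principal horizontal component of the residual.
#'
#' @param epoch a gait-labeled epoch.
#' @param gain complementary-filter accelerometer gain.
#' @return List with `linear` (n x 3, sensor frame), `ap` (numeric AP
#'   series), `ap_dir`, `gravity`.
#' @export
linear_acceleration <- function(epoch, gain = 0.02) {
  if (!identical(epoch$label, "gait")) {
    stop("contract violation: linear_acceleration requires a gait epoch",
         call. = FALSE)
  }
  .linear_core(epoch$acc, epoch$gyr, epoch$rate, gain)
}

# stance segmentation on raw arrays; returns index intervals
.zupt_core <- function(acc, gyr, rate, still_threshold = 1.0,
                       gyro_threshold = 0.5, min_still = 0.08) {
  n <- nrow(acc)
  if (!is.null(gyr)) {
    stat <- moving_average(sqrt(rowSums(gyr^2)), 0.04 * rate)
    thr <- gyro_threshold
  } else {
    # deviation from the (per-axis median) gravity vector; the median is
    # robust on 10 s slices where a 0.25 Hz low-pass is mostly transient
    dev <- sweep(acc, 2, apply(acc, 2, median))
    stat <- moving_average(sqrt(rowSums(dev^2)), 0.04 * rate)
    thr <- still_threshold
  }
  still <- stat < thr
  r <- rle(as.vector(still))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & r$lengths >= min_still * rate
  stance <- cbind(starts[ok], ends[ok])
  # swing = complement; stance and swing tile the epoch exactly
  swing <- NULL
  if (nrow(stance) == 0) {
    swing <- matrix(c(1L, n), 1)
  } else {
    if (stance[1, 1] > 1) swing <- rbind(swing, c(1L, stance[1, 1]))
    if (nrow(stance) > 1) {
      for (i in seq_len(nrow(stance) - 1)) {
        swing <- rbind(swing, c(stance[i, 2], stance[i + 1, 1]))
      }
    }
    if (stance[nrow(stance), 2] < n) {
      swing <- rbind(swing, c(stance[nrow(stance), 2], n))
    }
    if (is.null(swing)) swing <- matrix(integer(0), 0, 2)
  }
  list(stance = stance, swing = swing)
}

#' ZUPT stance/swing segmentation
#'
#' Stance phases are maximal intervals where the detection statistic stays
#' below threshold for at least `min_still` seconds; swing is the
#' complement, so the two tile the epoch. The statistic is the smoothed
#' angular-rate norm when a gyroscope is present, otherwise the smoothed
#' magnitude of the acceleration's deviation from the gravity vector
#' (per-axis median). Integrated velocity is reset to zero at each stance
#' (the
#' zero-velocity constraint consumed by [epoch_speed()]).
#'
#' @param epoch a gait-labeled epoch.
#' @param still_threshold acceleration-deviation threshold (m/s^2).
#' @param gyro_threshold angular-rate threshold (rad/s).
#' @param min_still minimum stance duration (s).
#' @return List with integer index intervals `stance` and `swing`
#'   (two-column matrices). If no stance is found a `no-zupt` warning is
#'   raised and `stance` has zero rows (the epoch's speed is then not
#'   computable).
#' @export
zupt_segment <- function(epoch, still_threshold = 1.0, gyro_threshold = 0.5,
                         min_still = 0.08) {
  if (!identical(epoch$label, "gait")) {
    stop("contract violation: zupt_segment requires a gait epoch",
         call. = FALSE)
  }
  z <- .zupt_core(epoch$acc, epoch$gyr, epoch$rate, still_threshold,
                  gyro_threshold, min_still)
  if (nrow(z$stance) == 0) {
    warning("no-zupt: no stance interval found; speed not computable",
            call. = FALSE)
  }
  z
}

# integrate one swing: velocity from zero (ZUPT), linear velocity detrend
# anchored at both stance boundaries, |displacement|
.swing_displacement <- function(ap, rate, drift_correct = TRUE) {
  nn <- length(ap)
  if (nn < 3) return(0)
  v <- cumsum(c(0, (ap[-1] + ap[-nn]) / 2)) / rate
  if (drift_correct) {
    v <- v - v[nn] * (seq_len(nn) - 1) / (nn - 1)
  }
  sum((v[-1] + v[-nn]) / 2) / rate
}

#' Gait speed of one epoch by ZUPT double integration
#'
#' Per swing, the AP linear acceleration is integrated to velocity
#' (starting from zero at the stance anchor), drift-corrected by removing
#' the linear velocity trend forced to zero at both anchors, and
#' integrated again to displacement. The epoch distance is the sum of
#' absolute per-swing displacements; speed is distance over the epoch
#' duration.
#'
#' @param epoch a gait-labeled epoch.
#' @param swing two-column matrix of swing index intervals (from
#'   [zupt_segment()]).
#' @param ap AP linear-acceleration series (from [linear_acceleration()]).
#' @param drift_correct apply the per-swing linear velocity detrend.
#' @return Speed in m/s, or `NA` if there is no swing to integrate.
#' @export
epoch_speed <- function(epoch, swing, ap, drift_correct = TRUE) {
  if (is.null(swing) || nrow(swing) == 0) return(NA_real_)
  dist <- 0
  for (i in seq_len(nrow(swing))) {
    seg <- ap[swing[i, 1]:swing[i, 2]]
    dist <- dist + abs(.swing_displacement(seg, epoch$rate, drift_correct))
  }
  dist / (length(epoch$time) / epoch$rate)
}

# run-level speed estimation: segment and integrate over a contiguous run
# of gait epochs so swings straddling epoch boundaries stay intact; each
# swing's displacement is attributed to the epoch containing its midpoint
.run_speeds <- function(epochs, run, still_threshold = 1.0,
                        gyro_threshold = 0.5, min_still = 0.08) {
  acc <- do.call(rbind, lapply(epochs[run], `[[`, "acc"))
  gyr <- if (is.null(epochs[[run[1]]]$gyr)) NULL else
    do.call(rbind, lapply(epochs[run], `[[`, "gyr"))
  rate <- epochs[[run[1]]]$rate
  spe <- nrow(epochs[[run[1]]]$acc)
  lin <- .linear_core(acc, gyr, rate)
  z <- .zupt_core(acc, gyr, rate, still_threshold, gyro_threshold, min_still)
  dist <- rep(0, length(run))
  if (nrow(z$stance) == 0) return(rep(NA_real_, length(run)))
  for (i in seq_len(nrow(z$swing))) {
    seg <- lin$ap[z$swing[i, 1]:z$swing[i, 2]]
    d <- abs(.swing_displacement(seg, rate))
    ep <- (floor((z$swing[i, 1] + z$swing[i, 2]) / 2) - 1) %/% spe + 1
    ep <- min(max(ep, 1L), length(run))
    dist[ep] <- dist[ep] + d
  }
  dist / (spe / rate)
}
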
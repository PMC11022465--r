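# 2MWT gait features: the four families of the catalog. All emitters return
# a `feature_vector` data.frame (feature, value, units, family, sensor)
# whose names are drawn from feature_registry().

.fv <- function(values) {
  reg <- feature_registry()
  nm <- names(values)
  bad <- setdiff(nm, reg$name)
  if (length(bad)) {
    stop("features not in registry: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- reg[match(nm, reg$name), ]
  out$value <- as.numeric(values)
  rownames(out) <- NULL
  structure(out[, c("name", "value", "units", "family", "sensor")],
            class = c("feature_vector", "data.frame"))
}

.cv <- function(x) if (mean(x) == 0) NA_real_ else sd(x) / mean(x)

# strides longer than `turn_factor` x the median are treated as turning
# segments on the short walking path and excluded from stride statistics
.usable <- function(stride_times, turn_factor = 1.5) {
  stride_times[stride_times <= turn_factor * median(stride_times)]
}

#' Spatiotemporal gait features
#'
#' Stride/step timing statistics, stance and swing fractions, cadence, gait
#' speed and mean stride length from detected gait events. Gait speed is
#' distance walked / elapsed time; supply the walked distance directly via
#' `measured_distance`, or it is inferred as `path_length` times the number
#' of path traversals (turn-flagged stride clusters + 1). Strides longer
#' than 1.5x the median stride are flagged as turns and excluded from the
#' stride statistics.
#'
#' @param events a `gait_events` object.
#' @param path_length walking-path length in meters (default 14).
#' @param duration elapsed test time in seconds (defaults to the event
#'   span).
#' @param measured_distance total distance walked in meters, if known.
#' @return A `feature_vector`.
#' @export
compute_spatiotemporal <- function(events, path_length = 14, duration = NULL,
                                   measured_distance = NULL) {
  stopifnot(inherits(events, "gait_events"))
  if (path_length <= 0) stop("path_length must be > 0", call. = FALSE)
  if (is.null(duration)) duration <- diff(attr(events, "span"))
  strides <- c(diff(events$left_foot$ic), diff(events$right_foot$ic))
  n_turn <- sum(strides > 1.5 * median(strides))
  strides <- .usable(strides)
  if (!length(strides)) stop("insufficient gait: zero usable strides",
                             call. = FALSE)
  steps <- .step_times(events)
  step_all <- c(steps$left, steps$right)
  stance <- swing <- numeric(0)
  for (foot in c("left_foot", "right_foot")) {
    e <- events[[foot]]
    k <- min(length(e$ic), length(e$fc) - 0)
    sw <- e$ic - e$fc                      # swing i: fc_i -> ic_i
    st <- e$fc[-1] - e$ic[-length(e$ic)]   # stance i: ic_i -> fc_{i+1}
    strd <- diff(e$ic)
    ok <- strd <= 1.5 * median(strd)
    stance <- c(stance, (st / strd)[ok])
    swing <- c(swing, (sw[-1] / strd)[ok])
  }
  if (!is.null(measured_distance)) {
    distance <- measured_distance
  } else {
    distance <- path_length * (n_turn + 1)
  }
  speed <- distance / duration
  .fv(c(gait_speed = speed,
        stride_time_mean = mean(strides),
        stride_time_sd = sd(strides),
        stride_time_cv = .cv(strides),
        step_time_mean = mean(step_all),
        step_time_sd = sd(step_all),
        step_time_cv = .cv(step_all),
        stride_length_mean = speed * mean(strides),
        cadence = 60 / mean(step_all),
        stance_fraction = mean(stance),
        swing_fraction = mean(swing)))
}

#' Frequency-domain trunk features
#'
#' Per trunk axis (AP, ML, vertical): dominant frequency (Welch periodogram
#' peak in 0.3-5 Hz) and its amplitude, index of harmonicity (power at the
#' dominant frequency over the summed power of its first six harmonics),
#' and the harmonic ratio over the first 20 harmonics of stride frequency
#' (even/odd harmonic magnitudes for AP and vertical, odd/even for ML).
#'
#' @param recording a preprocessed [imu_recording()] with a `low_back`
#'   sensor.
#' @param events a `gait_events` object (supplies stride frequency).
#' @return A `feature_vector`.
#' @export
compute_frequency <- function(recording, events) {
  s <- recording$sensors[["low_back"]]
  if (is.null(s)) stop("low_back sensor required", call. = FALSE)
  rate <- recording$rate
  axes <- list(ap = s$acc[, 1], ml = s$acc[, 2], v = s$acc[, 3])
  degenerate <- names(axes)[vapply(axes, sd, 0) < 1e-9]
  if (length(degenerate)) {
    stop("undefined features (constant signal): ",
         paste(unlist(lapply(degenerate, function(a)
           paste0(c("dominant_freq_", "dominant_amp_", "harmonicity_index_",
                    "harmonic_ratio_"), a))), collapse = ", "),
         call. = FALSE)
  }
  f_stride <- 1 / mean(c(diff(events$left_foot$ic),
                         diff(events$right_foot$ic)))
  vals <- c()
  for (ax in names(axes)) {
    x <- axes[[ax]] - mean(axes[[ax]])
    ps <- welch_psd(x, rate)
    band <- ps$freq >= 0.3 & ps$freq <= 5
    f_bin <- ps$freq[band][which.max(ps$psd[band])]
    # refine within one periodogram bin by maximizing the projected
    # amplitude (the Welch grid is too coarse for amplitude readout)
    df <- ps$freq[2] - ps$freq[1]
    f_grid <- seq(max(0.3, f_bin - df), min(5, f_bin + df), length.out = 41)
    amps <- vapply(f_grid, function(f) harmonic_amplitude(x, rate, f), 0)
    f_dom <- f_grid[which.max(amps)]
    amp <- max(amps)
    ph <- sapply(1:6, function(h) harmonic_amplitude(x, rate, h * f_dom)^2 / 2)
    ih <- ph[1] / sum(ph)
    hh <- sapply(1:20, function(h) harmonic_amplitude(x, rate, h * f_stride))
    even <- sum(hh[seq(2, 20, by = 2)])
    odd <- sum(hh[seq(1, 19, by = 2)])
    hr <- if (ax == "ml") odd / even else even / odd
    v <- c(f_dom, amp, ih, hr)
    names(v) <- paste0(c("dominant_freq_", "dominant_amp_",
                         "harmonicity_index_", "harmonic_ratio_"), ax)
    vals <- c(vals, v)
  }
  .fv(vals)
}

#' Sample entropy of a series
#'
#' Template length `m`, tolerance `r` (Chebyshev distance), self-matches
#' excluded.
#'
#' @param x numeric series.
#' @param m template length (default 2).
#' @param r tolerance in signal units (default `0.2 * sd(x)`).
#' @return Sample entropy (dimensionless), `NA` if no matches.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  if (r <= 0) stop("tolerance r must be > 0", call. = FALSE)
  .sampen_cpp(as.numeric(x), as.integer(m), r)
}

# unbiased autocorrelation normalized to lag 0
.unbiased_acf <- function(x, max_lag) {
  n <- length(x)
  a <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE,
                      demean = TRUE)$acf)
  lags <- 0:max_lag
  a * n / (n - lags) / (a[1] * n / n)
}

#' Complexity / regularity trunk features
#'
#' Per trunk axis: sample entropy (m = 2, r = 0.2 x SD, on the 100 Hz
#' series) and step/stride regularity — the first and second dominant peaks
#' of the unbiased autocorrelation normalized to lag zero — plus their
#' ratio (regularity symmetry).
#'
#' @param recording a preprocessed [imu_recording()] with a `low_back`
#'   sensor and at least 60 s of data.
#' @param max_lag_s autocorrelation search horizon in seconds.
#' @return A `feature_vector`.
#' @export
compute_complexity <- function(recording, max_lag_s = 4) {
  s <- recording$sensors[["low_back"]]
  if (is.null(s)) stop("low_back sensor required", call. = FALSE)
  rate <- recording$rate
  n <- length(s$time)
  if (n < 10 * max_lag_s * rate) {
    stop("too short: need >= 10x the autocorrelation lag searched",
         call. = FALSE)
  }
  axes <- list(ap = s$acc[, 1], ml = s$acc[, 2], v = s$acc[, 3])
  vals <- c()
  for (ax in names(axes)) {
    x <- axes[[ax]] - mean(axes[[ax]])
    if (sd(x) < 1e-12) {
      stop("undefined features (constant signal, r = 0): ",
           paste0(c("sample_entropy_", "stride_regularity_",
                    "step_regularity_", "regularity_symmetry_"), ax,
                  collapse = ", "), call. = FALSE)
    }
    se <- sample_entropy(x)
    ac <- .unbiased_acf(x, round(max_lag_s * rate))
    pk <- find_signal_peaks(ac, rate, prominence = 0.05, min_sep = 0.25)
    pk <- pk[pk > 0.25 * rate]  # skip the lag-0 shoulder
    step_reg <- if (length(pk) >= 1) ac[pk[1]] else NA_real_
    stride_reg <- if (length(pk) >= 2) ac[pk[2]] else NA_real_
    v <- c(se, stride_reg, step_reg,
           if (is.na(step_reg) || is.na(stride_reg)) NA_real_
           else step_reg / stride_reg)
    names(v) <- paste0(c("sample_entropy_", "stride_regularity_",
                         "step_regularity_", "regularity_symmetry_"), ax)
    vals <- c(vals, v)
  }
  .fv(vals)
}

#' Asymmetry features
#'
#' Symmetry index `SI = |L - R| / (0.5 (L + R)) x 100%` and the ordered
#' max/min left-right ratio for step, stance and swing time.
#'
#' @param events a `gait_events` object with >= 4 strides per foot.
#' @return A `feature_vector`.
#' @export
compute_asymmetry <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  for (foot in c("left_foot", "right_foot")) {
    if (is.null(events[[foot]]) || length(events[[foot]]$ic) < 2) {
      stop("missing side: ", foot, " has no usable events", call. = FALSE)
    }
    if (length(events[[foot]]$ic) < 5) {
      stop("insufficient gait: need >= 4 strides per foot", call. = FALSE)
    }
  }
  steps <- .step_times(events)
  side_mean <- function(foot, what) {
    e <- events[[foot]]
    sw <- e$ic - e$fc
    st <- e$fc[-1] - e$ic[-length(e$ic)]
    switch(what, swing = mean(sw), stance = mean(st))
  }
  si <- function(l, r) abs(l - r) / (0.5 * (l + r)) * 100
  rat <- function(l, r) max(l, r) / min(l, r)
  lst <- mean(steps$left); rst <- mean(steps$right)
  lsta <- side_mean("left_foot", "stance")
  rsta <- side_mean("right_foot", "stance")
  lsw <- side_mean("left_foot", "swing")
  rsw <- side_mean("right_foot", "swing")
  .fv(c(si_step_time = si(lst, rst),
        si_stance_time = si(lsta, rsta),
        si_swing_time = si(lsw, rsw),
        ratio_step_time = rat(lst, rst),
        ratio_stance_time = rat(lsta, rsta),
        ratio_swing_time = rat(lsw, rsw)))
}

#' Extract the full gait-feature vector from a 2MWT recording
#'
#' Runs preprocessing (unless already done), gait-event detection and all
#' four feature families. The result always includes `gait_speed` and all
#' values are finite.
#'
#' @param recording an [imu_recording()] with both feet and low back.
#' @param path_length walking-path length in meters.
#' @param measured_distance total distance walked in meters (defaults to
#'   the recording's `distance_m` metadata when present).
#' @param ... passed to [detect_gait_events()].
#' @return A `feature_vector` data.frame (feature, value, units, family,
#'   sensor).
#' @export
#' @examples
#' g <- generate_2mwt_signals(gait_truth(), duration = 60, seed = 3)
#' fv <- extract_features(g$recording)
#' fv[fv$name == "gait_speed", ]
extract_features <- function(recording, path_length = 14,
                             measured_distance = NULL, ...) {
  duration <- recording_duration(recording)
  if (!isTRUE(recording$meta$preprocessed)) {
    recording <- preprocess(recording)
  }
  if (is.null(measured_distance)) {
    measured_distance <- recording$meta$distance_m
  }
  events <- detect_gait_events(recording, ...)
  fv <- rbind(
    compute_spatiotemporal(events, path_length = path_length,
                           duration = duration,
                           measured_distance = measured_distance),
    compute_frequency(recording, events),
    compute_complexity(recording),
    compute_asymmetry(events))
  bad <- fv$name[!is.finite(fv$value)]
  if (length(bad)) {
    stop("non-finite feature values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  class(fv) <- c("feature_vector", "data.frame")
  fv
}

#' Write / read a feature vector as delimited text
#'
#' @param fv a `feature_vector`.
#' @param path output file.
#' @param measurement_id identifier written with every row.
#' @return `write_feature_vector` returns `path` invisibly;
#'   `read_feature_vector` the reconstructed `feature_vector`.
#' @export
write_feature_vector <- function(fv, path, measurement_id = "m001") {
  df <- cbind(measurement_id = measurement_id, as.data.frame(fv))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_vector
#' @export
read_feature_vector <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  structure(df[, c("name", "value", "units", "family", "sensor")],
            class = c("feature_vector", "data.frame"))
}
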
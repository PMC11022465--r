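# Preprocessing, gait-event detection and the four feature families.

test_that("preprocessing is the identity for clean 100 Hz input", {
  t <- seq(0, 10, by = 0.01)
  acc <- cbind(sin(t), cos(t), GRAVITY + 0 * t)
  gyr <- matrix(0, length(t), 3)
  rec <- imu_recording(list(low_back = list(time = t, acc = acc, gyr = gyr)),
                       rate = 100)
  out <- preprocess(rec)
  expect_equal(out$sensors$low_back$acc, acc, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(max(abs(out$sensors$low_back$gyr)), 0, tolerance = 1e-9)
})

test_that("a constant gyroscope bias is removed on stationary data", {
  t <- seq(0, 10, by = 0.01)
  n <- length(t)
  acc <- cbind(numeric(n), numeric(n), rep(GRAVITY, n))
  bias <- c(0.05, -0.2, 0.11)
  gyr <- matrix(rep(bias, each = n), n, 3)
  rec <- imu_recording(list(calf = list(time = t, acc = acc, gyr = gyr)),
                       rate = 100)
  out <- preprocess(rec)
  expect_lt(max(abs(colMeans(out$sensors$calf$gyr))), 1e-6)
})

test_that("resampling 104 Hz onto 100 Hz reproduces an analytic sinusoid", {
  t <- (0:(104 * 10 - 1)) / 104
  f <- 1.7
  acc <- cbind(sin(2 * pi * f * t), numeric(length(t)),
               rep(GRAVITY, length(t)))
  rec <- imu_recording(list(low_back = list(time = t, acc = acc,
                                            gyr = NULL)), rate = 104)
  out <- preprocess(rec)
  grid <- out$sensors$low_back$time
  expected <- sin(2 * pi * f * grid)
  rms_err <- sqrt(mean((out$sensors$low_back$acc[, 1] - expected)^2))
  expect_lt(rms_err / sqrt(mean(expected^2)), 0.01)
})

test_that("preprocess rejects recordings shorter than 2 s", {
  t <- seq(0, 1, by = 0.01)
  rec <- imu_recording(list(calf = list(
    time = t, acc = matrix(GRAVITY, length(t), 3), gyr = NULL)), rate = 100)
  expect_error(preprocess(rec), "too short")
})

test_that("event detection recovers stride timing and asymmetry", {
  g <- fixture_2mwt()  # stride 1.2 s, speed 0.8
  ev <- detect_gait_events(preprocess(g$recording))
  expect_lt(abs(mean(diff(ev$left_foot$ic)) - 1.2), 0.01)
  expect_lt(abs(mean(diff(ev$right_foot$ic)) - 1.2), 0.01)
  # invariants: alternating, inside the span
  for (foot in c("left_foot", "right_foot")) {
    e <- ev[[foot]]
    expect_true(all(diff(e$ic) > 0))
    expect_true(all(e$fc < e$ic))
    expect_true(all(e$ic <= attr(ev, "span")[2]))
  }

  ga <- generate_2mwt_signals(gait_truth(stride_time = 1.2,
                                         asymmetry_ratio = 1.2),
                              duration = 120, seed = 13)
  eva <- detect_gait_events(preprocess(ga$recording))
  st <- strollpipe:::.step_times(eva)
  ratio <- max(mean(st$left), mean(st$right)) /
    min(mean(st$left), mean(st$right))
  expect_lt(abs(ratio - 1.2), 0.05)
})

test_that("a stationary recording raises an insufficient-gait error", {
  t <- seq(0, 20, by = 0.01)
  n <- length(t)
  quiet <- list(time = t, acc = matrix(c(0, 0, GRAVITY), n, 3,
                                       byrow = TRUE),
                gyr = matrix(0, n, 3))
  rec <- imu_recording(list(left_foot = quiet, right_foot = quiet),
                       rate = 100)
  expect_error(detect_gait_events(rec), "insufficient gait")
})

test_that("spatiotemporal features follow their defining arithmetic", {
  g <- fixture_2mwt()
  ev <- detect_gait_events(preprocess(g$recording))
  fv <- compute_spatiotemporal(ev, duration = 60, measured_distance = 48)
  val <- setNames(fv$value, fv$name)
  expect_equal(unname(val["gait_speed"]), 0.8)
  # stride length = speed x stride time
  expect_equal(unname(val["stride_length_mean"]),
               0.8 * val[["stride_time_mean"]])
  expect_lt(abs(val[["stride_time_mean"]] - 1.2), 0.01)
  expect_lt(val[["stride_time_cv"]], 0.02)  # cv = 0 truth
  expect_equal(unname(val["cadence"]), 60 / val[["step_time_mean"]])
})

test_that("stride-time CV propagates from truth to feature", {
  g <- generate_2mwt_signals(gait_truth(stride_time = 1.0,
                                        stride_time_cv = 0.1),
                             duration = 120, seed = 21)
  ev <- detect_gait_events(preprocess(g$recording))
  fv <- compute_spatiotemporal(ev, measured_distance = 100)
  cv <- fv$value[fv$name == "stride_time_cv"]
  expect_lt(abs(cv - 0.1), 0.03)
})

test_that("turn-flagged strides are excluded from stride statistics", {
  mk <- function(ic) list(ic = ic, fc = ic - 0.4)
  ic <- cumsum(c(1, rep(1, 10), 2.5, rep(1, 10)))  # one turn stride
  ev <- structure(list(left_foot = mk(ic), right_foot = mk(ic + 0.5)),
                  class = "gait_events", span = c(0, max(ic) + 1))
  fv <- compute_spatiotemporal(ev, duration = 30, measured_distance = 20)
  expect_equal(fv$value[fv$name == "stride_time_mean"], 1)
  expect_equal(fv$value[fv$name == "stride_time_sd"], 0)
})

test_that("frequency features resolve a pure tone and its harmonics", {
  t <- seq(0, 60 - 0.01, by = 0.01)
  n <- length(t)
  mk_rec <- function(v_axis, ap_axis = NULL) {
    if (is.null(ap_axis)) ap_axis <- 0.3 * sin(2 * pi * 1.3 * t)
    acc <- cbind(ap_axis, 0.2 * sin(2 * pi * 0.9 * t), GRAVITY + v_axis)
    r <- imu_recording(list(low_back = list(time = t, acc = acc,
                                            gyr = NULL)), rate = 100)
    r$meta$preprocessed <- TRUE
    r
  }
  ev <- structure(list(left_foot = list(ic = seq(1, 59, by = 1),
                                        fc = seq(0.6, 58.6, by = 1)),
                       right_foot = list(ic = seq(1.5, 59.5, by = 1),
                                         fc = seq(1.1, 59.1, by = 1))),
                  class = "gait_events", span = c(0, 60))
  rec <- mk_rec(2 * sin(2 * pi * 2 * t))  # stride freq 1 Hz
  fv <- compute_frequency(rec, ev)
  val <- setNames(fv$value, fv$name)
  expect_lt(abs(val[["dominant_freq_v"]] - 2), 0.05)
  expect_gte(val[["harmonicity_index_v"]], 0.95)
  expect_lt(abs(val[["dominant_amp_v"]] - 2), 0.05)

  # equal-amplitude 1 + 2 Hz on AP with stride frequency 1 Hz:
  # one odd (h=1) and one even (h=2) harmonic -> harmonic ratio ~ 1
  rec2 <- mk_rec(2 * sin(2 * pi * 2 * t),
                 ap_axis = sin(2 * pi * 1 * t) + sin(2 * pi * 2 * t))
  fv2 <- compute_frequency(rec2, ev)
  hr <- fv2$value[fv2$name == "harmonic_ratio_ap"]
  expect_lt(abs(hr - 1), 0.05)
})

test_that("white-noise frequency features stay finite with a small peak", {
  ev <- structure(list(left_foot = list(ic = seq(1, 59, by = 1.2),
                                        fc = seq(0.6, 58.6, by = 1.2)),
                       right_foot = list(ic = seq(1.6, 59.6, by = 1.2),
                                         fc = seq(1.2, 59.2, by = 1.2))),
                  class = "gait_events", span = c(0, 60))
  t <- seq(0, 60 - 0.01, by = 0.01)
  rel <- vapply(1:25, function(s) {
    acc <- withr::with_seed(s, matrix(rnorm(length(t) * 3), ncol = 3))
    acc[, 3] <- acc[, 3] + GRAVITY
    rec <- imu_recording(list(low_back = list(time = t, acc = acc,
                                              gyr = NULL)), rate = 100)
    rec$meta$preprocessed <- TRUE
    fv <- compute_frequency(rec, ev)
    expect_true(all(is.finite(fv$value)))
    amp <- fv$value[fv$name == "dominant_amp_v"]
    amp^2 / 2  # power at the "dominant" peak, vs unit total power
  }, 0)
  # a genuine peak would carry order-one power; noise peaks carry little
  expect_lt(median(rel), 0.25)
})

test_that("complexity features: periodicity, noise ordering, degeneracy", {
  t <- seq(0, 80 - 0.01, by = 0.01)
  n <- length(t)
  mk <- function(sig) {
    acc <- cbind(sig, sig, GRAVITY + sig)
    r <- imu_recording(list(low_back = list(time = t, acc = acc,
                                            gyr = NULL)), rate = 100)
    r$meta$preprocessed <- TRUE
    r
  }
  per <- mk(sin(2 * pi * t / 1.2) + 0.5 * sin(2 * pi * 2 * t / 1.2))
  fv <- compute_complexity(per)
  expect_gte(fv$value[fv$name == "stride_regularity_v"], 0.99)

  # sample entropy of white noise exceeds that of an equal-SD sinusoid
  sino <- sin(2 * pi * t / 1.2)
  se_sin <- sample_entropy(sino)
  higher <- vapply(1:10, function(s) {
    noise <- withr::with_seed(s, rnorm(n, 0, sd(sino)))
    sample_entropy(noise) > se_sin
  }, TRUE)
  expect_true(all(higher))

  expect_error(compute_complexity(mk(rep(0, n))), "constant")
  short <- mk(sin(t))
  short$sensors$low_back <- lapply(short$sensors$low_back, function(x)
    if (is.matrix(x)) x[1:3000, ] else if (length(x) == n) x[1:3000] else x)
  expect_error(compute_complexity(short), "too short")
})

test_that("asymmetry features follow the symmetry-index formula", {
  mk <- function(ic, fc) list(ic = ic, fc = fc)
  # symmetric: L = R for everything
  ic_l <- seq(1, 20, by = 1.2); ic_r <- ic_l + 0.6
  ev <- structure(list(left_foot = mk(ic_l, ic_l - 0.45),
                       right_foot = mk(ic_r, ic_r - 0.45)),
                  class = "gait_events", span = c(0, 21))
  fv <- compute_asymmetry(ev)
  val <- setNames(fv$value, fv$name)
  expect_equal(unname(val[c("si_step_time", "si_stance_time",
                            "si_swing_time")]), rep(0, 3),
               tolerance = 1e-9)
  expect_equal(unname(val[c("ratio_step_time", "ratio_stance_time",
                            "ratio_swing_time")]), rep(1, 3),
               tolerance = 1e-9)

  # step times 0.66 / 0.54 -> SI = 20%
  ic_l2 <- seq(1, 20, by = 1.2); ic_r2 <- ic_l2 + 0.66
  ev2 <- structure(list(left_foot = mk(ic_l2, ic_l2 - 0.45),
                        right_foot = mk(ic_r2, ic_r2 - 0.45)),
                   class = "gait_events", span = c(0, 21))
  fv2 <- compute_asymmetry(ev2)
  expect_equal(fv2$value[fv2$name == "si_step_time"], 20,
               tolerance = 1e-6)
  expect_equal(fv2$value[fv2$name == "ratio_step_time"], 0.66 / 0.54,
               tolerance = 1e-6)
  # one-sided events
  ev3 <- structure(list(left_foot = mk(ic_l, ic_l - 0.45),
                        right_foot = mk(ic_r[1], ic_r[1] - 0.45)),
                   class = "gait_events", span = c(0, 21))
  expect_error(compute_asymmetry(ev3), "missing side")
})

test_that("noiseless end-to-end recovery within one sample period", {
  g <- generate_2mwt_signals(gait_truth(stride_time = 1.3,
                                        stride_length = 0.9),
                             duration = 60, noise_sd = 0, seed = 8)
  fv <- extract_features(g$recording)
  val <- setNames(fv$value, fv$name)
  expect_true(all(is.finite(fv$value)))
  expect_true("gait_speed" %in% fv$name)
  expect_lt(abs(val[["stride_time_mean"]] - 1.3), 0.01)
  expect_lt(abs(val[["step_time_mean"]] - 0.65), 0.01)
  expect_equal(unname(val[["gait_speed"]]), 0.9 / 1.3, tolerance = 1e-9)
  # swing widens by at most one sample on each side
  expect_lt(abs(val[["swing_fraction"]] - 0.4), 0.025)
})

test_that("resampling commutes with direct 100 Hz generation", {
  tr <- gait_truth(stride_time = 1.3, stride_length = 0.9)
  f104 <- extract_features(
    generate_2mwt_signals(tr, duration = 60, rate = 104, noise_sd = 0,
                          seed = 5)$recording)
  f100 <- extract_features(
    generate_2mwt_signals(tr, duration = 60, rate = 100, noise_sd = 0,
                          seed = 5)$recording)
  stopifnot(identical(f104$name, f100$name))
  tol <- pmax(0.02 * abs(f100$value), 0.05)  # floor covers % -scale SI
  # features whose truth is ~0, where one sample of jitter dominates
  expect_true(all(abs(f104$value - f100$value) <= tol))
})

test_that("feature vectors round-trip through delimited text", {
  g <- fixture_2mwt()
  fv <- extract_features(g$recording)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_vector(fv, path, measurement_id = "m007")
  back <- read_feature_vector(path)
  expect_equal(back$value, fv$value, tolerance = 1e-9)
  expect_identical(back$name, fv$name)
})
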
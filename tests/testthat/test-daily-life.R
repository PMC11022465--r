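# Daily-life chain: epoch splitting, classification, step counting, ZUPT
# integration, per-day summaries.

make_daily <- function(hours = 0.5, speed = 1.0, noise_sd = 0.3, seed = 1,
                       ...) {
  tl <- default_timeline(hours = hours,
                         gait_truth = gait_truth(gait_speed = speed), ...)
  generate_daily_recording(tl, noise_sd = noise_sd, seed = seed)
}

test_that("epoch splitting drops the trailing remainder", {
  tl <- activity_timeline("standing", 95, list(NULL))
  rec <- generate_daily_recording(tl, seed = 1)$recording
  eps <- split_epochs(rec)
  expect_length(eps, 9)
  starts <- vapply(eps, `[[`, 0, "start")
  expect_equal(starts, seq(0, 80, by = 10))

  tl2 <- activity_timeline("standing", 10, list(NULL))
  expect_length(split_epochs(generate_daily_recording(tl2,
                                                      seed = 1)$recording),
                1)
  tl3 <- activity_timeline("standing", 8, list(NULL))
  expect_error(split_epochs(generate_daily_recording(tl3,
                                                     seed = 1)$recording),
               "too short")
})

test_that("classifier separates gait, quiet wear and off-body epochs", {
  # pure-gravity constant epoch -> off_body
  tl <- activity_timeline(c("off_body", "gait", "sedentary"),
                          c(60, 60, 60),
                          list(NULL, gait_truth(gait_speed = 0.8), NULL))
  d <- generate_daily_recording(tl, seed = 3)
  eps <- classify_epochs(split_epochs(d$recording))
  labs <- vapply(eps, `[[`, "", "label")
  expect_true(all(labs[1:6] == "off_body"))
  expect_true(all(labs[7:12] == "gait"))
  expect_true(all(labs[13:18] == "non_gait"))
})

test_that("classifier accuracy is at least 0.90 on balanced days", {
  acc <- vapply(1:8, function(s) {
    tl <- default_timeline(hours = 0.5,
                           gait_truth = gait_truth(gait_speed = 0.8),
                           gait_fraction = 0.4, off_body_hours = 0.1)
    d <- generate_daily_recording(tl, seed = 100 + s)
    eps <- classify_epochs(split_epochs(d$recording))
    labs <- vapply(eps, `[[`, "", "label")
    # truth label per epoch midpoint from the timeline
    mids <- vapply(eps, `[[`, 0, "start") + 5
    ends <- cumsum(d$day_truth$bout_durations)
    truth <- d$day_truth$labels[findInterval(mids, c(0, ends),
                                             rightmost.closed = TRUE)]
    truth[truth %in% c("sedentary", "standing")] <- "non_gait"
    mean(labs == truth)
  }, 0)
  expect_true(all(acc >= 0.90))
})

test_that("step counts track day truth and are amplitude-invariant", {
  tl <- activity_timeline("gait", 600, list(gait_truth(stride_time = 1.2)))
  d <- generate_daily_recording(tl, noise_sd = 0.3, seed = 5)
  eps <- count_steps(classify_epochs(split_epochs(d$recording)))
  total <- sum(vapply(eps, `[[`, 0L, "steps"))
  expect_lt(abs(total - d$day_truth$steps), 20)  # truth = 1000

  # doubling the amplitude leaves the count unchanged
  rec2 <- d$recording
  rec2$sensors$calf$acc <- 2 * rec2$sensors$calf$acc
  eps2 <- count_steps(classify_epochs(split_epochs(rec2)))
  expect_equal(sum(vapply(eps2, `[[`, 0L, "steps")), total,
               tolerance = 0.02)

  # a day with no gait epochs counts zero steps
  tl0 <- activity_timeline("sedentary", 120, list(NULL))
  d0 <- generate_daily_recording(tl0, seed = 6)
  eps0 <- count_steps(classify_epochs(split_epochs(d0$recording)))
  expect_equal(sum(vapply(eps0, `[[`, 0L, "steps")), 0)
})

test_that("step recovery: 2% noiseless, 5% at noise 0.5", {
  tl <- activity_timeline("gait", 600, list(gait_truth()))
  for (cfg in list(c(0, 0.02), c(0.5, 0.05))) {
    d <- generate_daily_recording(tl, noise_sd = cfg[1], seed = 7)
    eps <- count_steps(classify_epochs(split_epochs(d$recording)))
    total <- sum(vapply(eps, `[[`, 0L, "steps"))
    expect_lt(abs(total - d$day_truth$steps) / d$day_truth$steps, cfg[2])
  }
})

test_that("linear acceleration removes gravity and respects mounting yaw", {
  # stationary upright epoch labeled gait (contract allows the call)
  t <- (0:519) / 52
  acc <- matrix(c(0, 0, GRAVITY), 520, 3, byrow = TRUE)
  ep <- structure(list(start = 0, time = t, acc = acc, gyr = NULL,
                       rate = 52, label = "gait", speed = NA, steps = NA),
                  class = "gait_epoch")
  lin <- linear_acceleration(ep)
  expect_lt(max(sqrt(rowSums(lin$linear^2))), 0.05)

  ep2 <- ep; ep2$label <- "non_gait"
  expect_error(linear_acceleration(ep2), "contract violation")

  # rotating the mounting 30 degrees about the vertical leaves the AP
  # principal-component magnitude unchanged
  tl <- activity_timeline("gait", 60, list(gait_truth(gait_speed = 1)))
  d <- generate_daily_recording(tl, seed = 8)
  eps <- classify_epochs(split_epochs(d$recording))
  ep3 <- eps[[3]]
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ep4 <- ep3; ep4$acc <- ep3$acc %*% t(R)
  a1 <- linear_acceleration(ep3)
  a2 <- linear_acceleration(ep4)
  expect_equal(sd(a2$ap), sd(a1$ap), tolerance = 0.02)
})

test_that("recovered AP series correlates with the generating waveform", {
  tl <- activity_timeline("gait", 60, list(gait_truth(gait_speed = 1)))
  d <- generate_daily_recording(tl, noise_sd = 0.1, seed = 12)
  eps <- classify_epochs(split_epochs(d$recording))
  ep <- eps[[3]]
  lin <- linear_acceleration(ep)
  truth_ap <- ep$acc[, 1] - mean(ep$acc[, 1])  # generator puts AP on x
  expect_gt(abs(cor(lin$ap, truth_ap)), 0.9)
})

test_that("ZUPT stance fraction matches truth and tiles the epoch", {
  tl <- activity_timeline("gait", 120, list(gait_truth(stride_time = 1.2,
                                                       gait_speed = 1)))
  d <- generate_daily_recording(tl, stance_fraction = 0.6, seed = 9)
  eps <- classify_epochs(split_epochs(d$recording))
  fracs <- vapply(eps[2:10], function(e) {
    z <- zupt_segment(e)
    sum(z$stance[, 2] - z$stance[, 1] + 1) / nrow(e$acc)
  }, 0)
  expect_lt(abs(mean(fracs) - 0.6), 0.05)

  z <- zupt_segment(eps[[3]])
  iv <- rbind(z$stance, z$swing)
  iv <- iv[order(iv[, 1]), ]
  expect_equal(iv[1, 1], 1)
  expect_equal(iv[nrow(iv), 2], nrow(eps[[3]]$acc))
  expect_true(all(iv[-1, 1] == iv[-nrow(iv), 2] |
                    iv[-1, 1] == iv[-nrow(iv), 2] + 1L))

  # constant-motion signal with no quiet intervals -> no-zupt warning
  tq <- (0:519) / 52
  wob <- 3 * sin(2 * pi * 1.5 * tq)
  epq <- structure(list(start = 0, time = tq,
                        acc = cbind(wob, wob, GRAVITY + wob), gyr = NULL,
                        rate = 52, label = "gait", speed = NA, steps = NA),
                   class = "gait_epoch")
  expect_warning(z2 <- zupt_segment(epq), "no-zupt")
  expect_equal(nrow(z2$stance), 0)
})

test_that("a single constant-acceleration swing integrates in closed form", {
  rate <- 1000
  n <- round(0.4 * rate)  # T = 0.4 s at 1 m/s^2
  ap <- rep(0, 3 * n)
  ap[(n + 1):(2 * n + 1)] <- 1
  ep <- structure(list(start = 0, time = (seq_len(3 * n) - 1) / rate,
                       acc = matrix(0, 3 * n, 3), gyr = NULL, rate = rate,
                       label = "gait", speed = NA, steps = NA),
                  class = "gait_epoch")
  swing <- matrix(c(n + 1L, 2L * n + 1L), 1)
  sp <- epoch_speed(ep, swing, ap, drift_correct = FALSE)
  disp <- sp * (3 * n / rate)
  expect_equal(disp, 0.5 * 1 * 0.4^2, tolerance = 1e-9)

  # AP identically zero during the swing -> zero speed
  expect_equal(epoch_speed(ep, swing, rep(0, 3 * n)), 0)
  # no swing -> not computable
  expect_true(is.na(epoch_speed(ep, matrix(numeric(0), 0, 2), ap)))
})

test_that("daily speeds are recovered within 10% with order preserved", {
  est <- vapply(c(0.6, 0.8, 1.0, 1.2), function(v) {
    d <- make_daily(hours = 0.5, speed = v, seed = 31)
    process_daily_recording(d$recording)$summary$avg_speed_mps[1]
  }, 0)
  expect_true(all(abs(est - c(0.6, 0.8, 1.0, 1.2)) /
                    c(0.6, 0.8, 1.0, 1.2) <= 0.1))
  expect_true(all(diff(est) > 0))
})

test_that("day summaries apply the speed floor and the 8-hour rule", {
  mk_ep <- function(start, label, speed = NA_real_, steps = 0L) {
    structure(list(start = start, time = start + (0:519) / 52,
                   acc = matrix(GRAVITY, 520, 3), gyr = NULL, rate = 52,
                   label = label, speed = speed, steps = steps),
              class = "gait_epoch")
  }
  eps <- c(
    lapply(seq(0, by = 10, length.out = 3), function(s)
      mk_ep(s, "gait", speed = c(0.04, 0.5, 0.7)[s / 10 + 1], steps = 10L)),
    lapply(seq(30, by = 10, length.out = 7), function(s)
      mk_ep(s, "non_gait")))
  sm <- summarize_day(eps)
  expect_equal(sm$avg_speed_mps, 0.6)  # 0.04 excluded
  expect_equal(sm$steps, 30)
  expect_false(sm$valid)  # 100 s of wear

  # exactly at the floor (0.05) is excluded too
  eps2 <- list(mk_ep(0, "gait", speed = 0.05), mk_ep(10, "gait", 0.5))
  expect_equal(summarize_day(eps2)$avg_speed_mps, 0.5)

  # 7.9 h of wear -> invalid; 8 h -> valid
  n79 <- ceiling(7.9 * 360)
  eps3 <- lapply(seq_len(n79) - 1, function(i) mk_ep(i * 10, "non_gait"))
  expect_false(summarize_day(eps3)$valid)
  eps4 <- lapply(seq_len(8 * 360) - 1, function(i) mk_ep(i * 10, "non_gait"))
  expect_true(summarize_day(eps4)$valid)

  # all epochs off body: zero wear, invalid, no speeds
  eps5 <- lapply(0:5, function(i) mk_ep(i * 10, "off_body"))
  sm5 <- summarize_day(eps5)
  expect_equal(sm5$wear_h, 0)
  expect_false(sm5$valid)
  expect_true(is.na(sm5$avg_speed_mps))
})

test_that("daily maximum speed is at least the average on valid days", {
  d <- make_daily(hours = 0.4, speed = 1.0, seed = 17,
                  gait_fraction = 0.5)
  sm <- process_daily_recording(d$recording)$summary
  expect_gte(sm$max_speed_mps, sm$avg_speed_mps)
})
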
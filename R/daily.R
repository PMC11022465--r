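#' Summarize labeled epochs into per-day walking-ability measures
#'
#' Wear time is 10 s per non-off-body epoch; a day is valid when wear time
#' reaches 8 hours. Gait epochs with speed at or below 0.05 m/s are
#' excluded (gait characteristics below that speed cannot be determined
#' reliably); the daily average gait speed is the mean of the remaining
#' epoch speeds and the daily maximum a high percentile of them (95th by
#' default; 1 gives the literal maximum). Steps are summed from the
#' per-epoch counts.
#'
#' @param epochs labeled epochs carrying `speed` and `steps` (see
#'   [process_daily_recording()]).
#' @param start_time_s clock time of the first epoch, seconds after
#'   midnight; day boundaries fall at local midnight.
#' @param max_percentile percentile (0-1] defining "maximum" gait speed.
#' @param speed_floor exclusion threshold in m/s (epochs with speed <=
#'   this value are dropped).
#' @param min_wear_h wear-time validity threshold in hours.
#' @return A data.frame with one row per calendar day: `day`,
#'   `avg_speed_mps`, `max_speed_mps`, `steps`, `wear_h`, `valid`.
#' @export
summarize_day <- function(epochs, start_time_s = 0, max_percentile = 0.95,
                          speed_floor = 0.05, min_wear_h = 8) {
  epoch_len <- length(epochs[[1]]$time) / epochs[[1]]$rate
  day_of <- vapply(epochs, function(e)
    floor((e$start + start_time_s) / 86400), 0)
  out <- lapply(sort(unique(day_of)), function(d) {
    eps <- epochs[day_of == d]
    labs <- vapply(eps, `[[`, "", "label")
    wear_h <- epoch_len * sum(labs != "off_body") / 3600
    sp <- vapply(eps, function(e) e$speed, 0)
    sp <- sp[labs == "gait" & !is.na(sp)]
    sp <- sp[sp > speed_floor]
    steps <- sum(vapply(eps, function(e)
      if (is.na(e$steps)) 0L else e$steps, 0L))
    data.frame(day = d,
               avg_speed_mps = if (length(sp)) mean(sp) else NA_real_,
               max_speed_mps = if (length(sp))
                 as.numeric(quantile(sp, max_percentile)) else NA_real_,
               steps = steps, wear_h = wear_h,
               valid = wear_h >= min_wear_h)
  })
  do.call(rbind, out)
}

#' Process a daily-life recording into walking-ability summaries
#'
#' Full daily-life chain: split into 10 s epochs, classify, count steps,
#' estimate per-epoch gait speed by ZUPT double integration (contiguous
#' gait epochs are segmented and integrated as one stretch so swings
#' crossing epoch boundaries stay intact), and summarize per calendar day.
#'
#' @param recording a single-sensor [imu_recording()].
#' @param classifier epoch classifier (default
#'   [default_gait_classifier()]).
#' @param ... passed on to [summarize_day()].
#' @return List with `summary` (per-day data.frame) and `epochs` (the
#'   labeled epochs with speeds and step counts).
#' @export
#' @examples
#' tl <- default_timeline(hours = 1, gait_truth(gait_speed = 1))
#' d <- generate_daily_recording(tl, seed = 1)
#' process_daily_recording(d$recording)$summary
process_daily_recording <- function(recording,
                                    classifier = default_gait_classifier(),
                                    ...) {
  epochs <- classify_epochs(split_epochs(recording), classifier)
  epochs <- count_steps(epochs)
  for (run in .gait_runs(epochs)) {
    sp <- .run_speeds(epochs, run)
    for (j in seq_along(run)) epochs[[run[j]]]$speed <- sp[j]
  }
  start_s <- recording$meta$start_time_s
  if (is.null(start_s)) start_s <- 0
  summary <- summarize_day(epochs, start_time_s = start_s, ...)
  list(summary = summary, epochs = epochs)
}

#' Write per-day walking-ability summaries as delimited text
#'
#' @param summary data.frame from [summarize_day()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_daily_summary <- function(summary, path) {
  write.table(summary, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
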
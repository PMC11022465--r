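#' Detect gait events from foot-mounted gyroscopes
#'
#' Mid-swing is located at the maxima of the sagittal angular rate (peak
#' prominence and minimum separation configurable); the initial contact of
#' each stride is the first zero crossing after mid-swing, the final
#' contact (toe-off) the last zero crossing before it. Events are returned
#' per foot with strictly increasing, alternating initial/final contacts.
#'
#' @param recording a preprocessed [imu_recording()] containing both
#'   `left_foot` and `right_foot` sensors with gyroscope data.
#' @param prominence minimum mid-swing peak prominence in rad/s.
#' @param min_sep minimum separation between mid-swing peaks in seconds.
#' @return An object of class `gait_events`: per foot a list with `ic` and
#'   `fc` (seconds), plus `midswing` peak times.
#' @export
#' @examples
#' g <- generate_2mwt_signals(gait_truth(), duration = 30, seed = 1)
#' ev <- detect_gait_events(preprocess(g$recording))
#' mean(diff(ev$left_foot$ic))
detect_gait_events <- function(recording, prominence = 0.5, min_sep = 0.4) {
  stopifnot(inherits(recording, "imu_recording"))
  need <- c("left_foot", "right_foot")
  if (!all(need %in% names(recording$sensors))) {
    stop("both foot sensors are required", call. = FALSE)
  }
  rate <- recording$rate
  out <- list()
  for (foot in need) {
    s <- recording$sensors[[foot]]
    if (is.null(s$gyr)) stop("foot sensor lacks gyroscope", call. = FALSE)
    gy <- s$gyr[, 2]  # sagittal axis (about y = mediolateral)
    pk <- find_signal_peaks(gy, rate, prominence = prominence,
                            min_sep = min_sep)
    pk <- pk[gy[pk] > 0]
    if (length(pk) < 4) {
      stop("insufficient gait: fewer than 4 strides detected on ", foot,
           call. = FALSE)
    }
    ic <- fc <- rep(NA_real_, length(pk))
    for (i in seq_along(pk)) {
      p <- pk[i]
      # first downward zero crossing after mid-swing
      j <- p
      while (j < length(gy) && gy[j + 1] > 0) j <- j + 1
      if (j < length(gy)) {
        ic[i] <- s$time[j] + (gy[j] / (gy[j] - gy[j + 1])) / rate
      }
      # last upward zero crossing before mid-swing
      j <- p
      while (j > 1 && gy[j - 1] > 0) j <- j - 1
      if (j > 1) {
        fc[i] <- s$time[j] - (gy[j] / (gy[j] - gy[j - 1])) / rate
      }
    }
    keep <- !is.na(ic) & !is.na(fc)
    ic <- ic[keep]; fc <- fc[keep]; ms <- s$time[pk[keep]]
    # enforce alternation: each swing is (fc_i, ic_i), fc_i > ic_{i-1}
    ok <- c(TRUE, fc[-1] > ic[-length(ic)])
    out[[foot]] <- list(ic = ic[ok], fc = fc[ok], midswing = ms[ok])
  }
  structure(out, class = "gait_events",
            span = range(recording$sensors[[1]]$time))
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-10s %d strides, mean stride time %.3f s\n", nm,
                length(x[[nm]]$ic), mean(diff(x[[nm]]$ic))))
  }
  invisible(x)
}

# merged step sequence: alternating initial contacts of the two feet,
# returning per-side step times (left = left IC -> right IC)
.step_times <- function(events) {
  lic <- events$left_foot$ic
  ric <- events$right_foot$ic
  all_ic <- rbind(data.frame(t = lic, side = "L"),
                  data.frame(t = ric, side = "R"))
  all_ic <- all_ic[order(all_ic$t), ]
  dt <- diff(all_ic$t)
  from <- all_ic$side[-nrow(all_ic)]
  to <- all_ic$side[-1]
  ok <- from != to  # drop doubled detections on the same side
  list(left = dt[ok & from == "L"], right = dt[ok & from == "R"])
}
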
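# Daily-life recordings are processed in consecutive non-overlapping
# 10-second epochs: classify (gait / non_gait / off_body), count steps,
# then estimate per-epoch gait speed by ZUPT double integration.

#' Split a recording into 10-second epochs
#'
#' @param recording a single-sensor [imu_recording()] of at least 10 s.
#' @param epoch_len epoch length in seconds (default 10).
#' @return A list of epoch objects (`start`, `time`, `acc`, `gyr`, `rate`,
#'   `label`, `speed`, `steps`); the trailing remainder shorter than
#'   `epoch_len` is dropped.
#' @export
#' @examples
#' tl <- activity_timeline("standing", 95, list(NULL))
#' length(split_epochs(generate_daily_recording(tl)$recording))  # 9
split_epochs <- function(recording, epoch_len = 10) {
  stopifnot(inherits(recording, "imu_recording"))
  s <- recording$sensors[[1]]
  rate <- recording$rate
  spe <- round(epoch_len * rate)
  n_ep <- floor(length(s$time) / spe)
  if (n_ep < 1) stop("too short: need >= ", epoch_len, " s", call. = FALSE)
  lapply(seq_len(n_ep), function(i) {
    idx <- ((i - 1) * spe + 1):(i * spe)
    structure(list(start = s$time[idx[1]], time = s$time[idx],
                   acc = s$acc[idx, , drop = FALSE],
                   gyr = if (is.null(s$gyr)) NULL
                         else s$gyr[idx, , drop = FALSE],
                   rate = rate, label = NA_character_,
                   speed = NA_real_, steps = NA_integer_),
              class = "gait_epoch")
  })
}

#' Default rule-based gait classifier
#'
#' Labels an epoch `off_body` when the acceleration-norm SD stays below a
#' stillness floor for the whole epoch, `gait` when the 0.5-3 Hz step-band
#' power fraction of the (demeaned) acceleration norm exceeds a threshold
#' and the SD exceeds an activity floor, and `non_gait` otherwise. Any
#' function mapping an epoch to one of those three labels may be
#' substituted for it in [classify_epochs()].
#'
#' @param band_fraction minimum step-band power fraction for gait.
#' @param activity_floor minimum acceleration-norm SD for gait (m/s^2).
#' @param stillness_floor below this SD the sensor counts as off body.
#' @return A function `epoch -> label`.
#' @export
default_gait_classifier <- function(band_fraction = 0.5,
                                    activity_floor = 0.3,
                                    stillness_floor = 0.02) {
  function(epoch) {
    nrm <- sqrt(rowSums(epoch$acc^2))
    s <- sd(nrm)
    if (s < stillness_floor) return("off_body")
    x <- nrm - mean(nrm)
    frac <- var(bandpass_filter(x, epoch$rate)) / var(x)
    if (frac > band_fraction && s > activity_floor) "gait" else "non_gait"
  }
}

#' Label epochs with an activity classifier
#'
#' @param epochs list of epochs from [split_epochs()].
#' @param classifier a function `epoch -> label`; defaults to
#'   [default_gait_classifier()].
#' @return The epochs with `label` filled in.
#' @export
classify_epochs <- function(epochs, classifier = default_gait_classifier()) {
  stopifnot(is.function(classifier))
  lapply(epochs, function(e) {
    lab <- classifier(e)
    if (!lab %in% c("gait", "non_gait", "off_body")) {
      stop("classifier returned invalid label: ", lab, call. = FALSE)
    }
    e$label <- lab
    e
  })
}

# maximal runs of consecutive gait epochs (indices)
.gait_runs <- function(epochs) {
  is_gait <- vapply(epochs, function(e) identical(e$label, "gait"), TRUE)
  r <- rle(is_gait)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  Map(function(s, e) s:e, starts[r$values], ends[r$values])
}

#' Count steps within gait epochs
#'
#' Steps are peaks of the band-passed (0.5-3 Hz) acceleration norm with a
#' minimum prominence and a minimum separation of 0.25 s. Contiguous gait
#' epochs are filtered as one segment (a step straddling an epoch boundary
#' is counted once); each peak is attributed to the epoch it falls in.
#'
#' @param epochs labeled epochs.
#' @param prominence minimum peak prominence in m/s^2.
#' @param min_sep minimum inter-step separation in seconds.
#' @return The epochs with per-epoch `steps` filled in (0 for non-gait).
#' @export
count_steps <- function(epochs, prominence = 1.5, min_sep = 0.25) {
  epochs <- lapply(epochs, function(e) { e$steps <- 0L; e })
  for (run in .gait_runs(epochs)) {
    acc <- do.call(rbind, lapply(epochs[run], `[[`, "acc"))
    rate <- epochs[[run[1]]]$rate
    nrm <- sqrt(rowSums(acc^2))
    pk <- find_signal_peaks(bandpass_filter(nrm, rate), rate,
                            prominence = prominence, min_sep = min_sep)
    spe <- nrow(epochs[[run[1]]]$acc)
    ep_of <- (pk - 1) %/% spe + 1
    tab <- table(ep_of)
    for (j in seq_along(tab)) {
      i <- run[as.integer(names(tab)[j])]
      epochs[[i]]$steps <- as.integer(tab[j])
    }
  }
  epochs
}
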
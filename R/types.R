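#' Ground-truth gait parameters for the synthetic generators
#'
#' Holds the stride-level truth a generated walking signal encodes. Exactly
#' two of `stride_time`, `stride_length` and `gait_speed` may be given; the
#' third is derived from `gait_speed = stride_length / stride_time`, which is
#' enforced at construction. Defaults reflect a sub-acute stroke cohort
#' (stride time 1.3 s, stride length 0.9 m, hence ~0.69 m/s).
#'
#' @param stride_time mean stride duration in seconds (> 0).
#' @param stride_length mean stride length in meters (> 0).
#' @param gait_speed walking speed in m/s; derived if `NULL`.
#' @param asymmetry_ratio left/right step-time ratio, >= 1.
#' @param stride_time_cv coefficient of variation of stride time, in [0, 0.5).
#' @return An object of class `gait_truth`.
#' @export
#' @examples
#' gait_truth(stride_time = 1.2, gait_speed = 0.8)
gait_truth <- function(stride_time = NULL, stride_length = NULL,
                       gait_speed = NULL, asymmetry_ratio = 1,
                       stride_time_cv = 0) {
  given <- c(stride_time = !is.null(stride_time),
             stride_length = !is.null(stride_length),
             gait_speed = !is.null(gait_speed))
  if (sum(given) == 0L) {
    stride_time <- 1.3
    stride_length <- 0.9
  } else if (sum(given) == 1L) {
    # fill in cohort-typical companions
    if (given[["stride_time"]]) stride_length <- 0.9
    if (given[["stride_length"]]) stride_time <- 1.3
    if (given[["gait_speed"]]) stride_time <- 1.3
  } else if (sum(given) == 3L) {
    if (abs(gait_speed - stride_length / stride_time) > 1e-9) {
      stop("gait_speed must equal stride_length / stride_time; ",
           "supply at most two of the three", call. = FALSE)
    }
  }
  if (is.null(gait_speed)) gait_speed <- stride_length / stride_time
  if (is.null(stride_length)) stride_length <- gait_speed * stride_time
  if (is.null(stride_time)) stride_time <- stride_length / gait_speed
  if (!is.finite(stride_time) || stride_time <= 0) {
    stop("stride_time must be positive", call. = FALSE)
  }
  if (!is.finite(stride_length) || stride_length <= 0) {
    stop("stride_length must be positive", call. = FALSE)
  }
  if (!is.finite(asymmetry_ratio) || asymmetry_ratio < 1) {
    stop("asymmetry_ratio must be >= 1", call. = FALSE)
  }
  if (!is.finite(stride_time_cv) || stride_time_cv < 0 ||
      stride_time_cv >= 0.5) {
    stop("stride_time_cv must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(stride_time = stride_time, stride_length = stride_length,
                 gait_speed = gait_speed, asymmetry_ratio = asymmetry_ratio,
                 stride_time_cv = stride_time_cv),
            class = "gait_truth")
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf(
    "<gait_truth> stride %.3g s x %.3g m -> %.3g m/s; asym %.3g; cv %.3g\n",
    x$stride_time, x$stride_length, x$gait_speed, x$asymmetry_ratio,
    x$stride_time_cv))
  invisible(x)
}

#' Daily-life activity timeline
#'
#' An ordered, contiguous sequence of activity bouts used by
#' [generate_daily_recording()]. Gait bouts carry their own [gait_truth()].
#'
#' @param labels character vector of bout labels, each one of
#'   `"gait"`, `"sedentary"`, `"standing"`, `"off_body"`.
#' @param durations bout durations in seconds, all > 0.
#' @param truths list parallel to `labels`; element must be a `gait_truth`
#'   where the label is `"gait"`, and is ignored (may be `NULL`) elsewhere.
#' @return An object of class `activity_timeline` with a `total_duration`
#'   attribute equal to `sum(durations)`.
#' @export
#' @examples
#' activity_timeline(c("sedentary", "gait"), c(300, 600),
#'                   list(NULL, gait_truth(gait_speed = 0.8)))
activity_timeline <- function(labels, durations, truths = NULL) {
  valid <- c("gait", "sedentary", "standing", "off_body")
  if (length(labels) == 0L) stop("timeline must have >= 1 bout", call. = FALSE)
  if (!all(labels %in% valid)) {
    stop("labels must be in {", paste(valid, collapse = ", "), "}",
         call. = FALSE)
  }
  if (length(durations) != length(labels) || any(!is.finite(durations)) ||
      any(durations <= 0)) {
    stop("durations must be positive and parallel to labels", call. = FALSE)
  }
  if (is.null(truths)) truths <- vector("list", length(labels))
  if (length(truths) != length(labels)) {
    stop("truths must be parallel to labels", call. = FALSE)
  }
  for (i in which(labels == "gait")) {
    if (is.null(truths[[i]])) truths[[i]] <- gait_truth()
    if (!inherits(truths[[i]], "gait_truth")) {
      stop("gait bouts need a gait_truth", call. = FALSE)
    }
  }
  structure(list(labels = labels, durations = durations, truths = truths),
            class = "activity_timeline",
            total_duration = sum(durations))
}

#' A balanced default daily timeline
#'
#' Convenience constructor for a timeline mixing gait and non-gait bouts;
#' used by tests and examples. Bout order is deterministic.
#'
#' @param hours total duration in hours.
#' @param gait_truth the [gait_truth()] shared by all gait bouts.
#' @param gait_fraction fraction of wear time spent walking.
#' @param off_body_hours trailing non-wear time in hours.
#' @return An `activity_timeline`.
#' @export
default_timeline <- function(hours = 9, gait_truth = strollpipe::gait_truth(),
                             gait_fraction = 0.25, off_body_hours = 0) {
  wear <- hours * 3600
  cycle <- 600  # 10-minute blocks
  n_cycles <- max(1L, floor(wear / cycle))
  gait_d <- cycle * gait_fraction
  labels <- character(0); durs <- numeric(0); truths <- list()
  others <- c("sedentary", "standing")
  for (i in seq_len(n_cycles)) {
    labels <- c(labels, "gait", others[1L + (i %% 2L)])
    durs <- c(durs, gait_d, cycle - gait_d)
    truths <- c(truths, list(gait_truth, NULL))
  }
  if (off_body_hours > 0) {
    labels <- c(labels, "off_body")
    durs <- c(durs, off_body_hours * 3600)
    truths <- c(truths, list(NULL))
  }
  activity_timeline(labels, durs, truths)
}

#' Specification of a synthetic longitudinal cohort
#'
#' Describes the latent-factor structure [generate_cohort()] plants: every
#' feature loads on a dominant latent walking-capacity factor (plus optional
#' minor factors), outcomes are driven by 2MWT gait speed with a planted
#' confounder path and a planted speed-by-covariate interaction, and repeated
#' sessions share a subject-level random intercept.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param sessions_per_subject repeated measurements per subject (>= 1).
#' @param latent_capacity_sd within-subject (session-level) SD of the latent
#'   capacity factor; the between-subject SD is fixed at 0.8 so the total
#'   latent variance is about 1 at the default 0.6.
#' @param feature_loadings numeric matrix (features x factors) of loadings,
#'   rownames = feature names; default: a 30-feature, 3-factor pattern with a
#'   dominant first factor (see [default_loadings()]).
#' @param confounder_strength path coefficient of the planted confounder on
#'   the outcome (its loading on the latent factor is fixed at 0.7).
#' @param modifier_strength coefficient of the speed-by-modifier interaction.
#' @param feature_noise_sd residual SD added to every feature.
#' @param outcome_noise_sd residual SD of the outcomes.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, sessions_per_subject = 3,
                        latent_capacity_sd = 0.6,
                        feature_loadings = default_loadings(),
                        confounder_strength = 0.06,
                        modifier_strength = 0.2,
                        feature_noise_sd = 0.35,
                        outcome_noise_sd = 0.05,
                        seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop("n_subjects must be >= 2", call. = FALSE)
  }
  if (sessions_per_subject < 1) {
    stop("sessions_per_subject must be >= 1", call. = FALSE)
  }
  sds <- c(latent_capacity_sd, feature_noise_sd, outcome_noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  if (is.null(dim(feature_loadings))) {
    feature_loadings <- matrix(feature_loadings,
                               ncol = 1,
                               dimnames = list(names(feature_loadings), NULL))
  }
  if (is.null(rownames(feature_loadings))) {
    stop("feature_loadings needs feature names as rownames", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 latent_capacity_sd = latent_capacity_sd,
                 feature_loadings = feature_loadings,
                 confounder_strength = confounder_strength,
                 modifier_strength = modifier_strength,
                 feature_noise_sd = feature_noise_sd,
                 outcome_noise_sd = outcome_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}
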
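# Catalog of the gait features the 2MWT stage emits. Representative of the
# four families (spatiotemporal, frequency, complexity, asymmetry); the
# registry is the single source of truth for names, units, family and sensor
# source, and is extensible without API change.

.registry_rows <- function() {
  st <- function(name, units) c(name, "spatiotemporal", units, "feet")
  fr <- function(name, units, axis) c(name, "frequency", units, "low_back")
  cx <- function(name, units) c(name, "complexity", units, "low_back")
  as_ <- function(name, units) c(name, "asymmetry", units, "feet")
  rows <- list(
    st("gait_speed", "m/s"),
    st("stride_time_mean", "s"),
    st("stride_time_sd", "s"),
    st("stride_time_cv", "-"),
    st("step_time_mean", "s"),
    st("step_time_sd", "s"),
    st("step_time_cv", "-"),
    st("stride_length_mean", "m"),
    st("cadence", "steps/min"),
    st("stance_fraction", "-"),
    st("swing_fraction", "-"))
  for (ax in c("ap", "v", "ml")) {
    rows <- c(rows, list(
      fr(paste0("dominant_freq_", ax), "Hz", ax),
      fr(paste0("dominant_amp_", ax), "m/s^2", ax),
      fr(paste0("harmonicity_index_", ax), "-", ax),
      fr(paste0("harmonic_ratio_", ax), "-", ax)))
  }
  for (ax in c("ap", "v", "ml")) {
    rows <- c(rows, list(
      cx(paste0("sample_entropy_", ax), "-"),
      cx(paste0("stride_regularity_", ax), "-"),
      cx(paste0("step_regularity_", ax), "-"),
      cx(paste0("regularity_symmetry_", ax), "-")))
  }
  rows <- c(rows, list(
    as_("si_step_time", "%"),
    as_("si_stance_time", "%"),
    as_("si_swing_time", "%"),
    as_("ratio_step_time", "-"),
    as_("ratio_stance_time", "-"),
    as_("ratio_swing_time", "-")))
  rows
}

#' The gait-feature registry
#'
#' Every feature the 2MWT extraction stage can emit, with its family
#' (`spatiotemporal`, `frequency`, `complexity`, `asymmetry`), units and
#' sensor source. Registry order is the canonical tie-break order used by
#' correlation pruning and component labelling.
#'
#' @return A data.frame with columns `name`, `family`, `units`, `sensor`.
#' @export
#' @examples
#' table(feature_registry()$family)
feature_registry <- function() {
  m <- do.call(rbind, .registry_rows())
  data.frame(name = m[, 1], family = m[, 2], units = m[, 3], sensor = m[, 4],
             stringsAsFactors = FALSE)
}

#' Default loading pattern for the synthetic cohort
#'
#' A 30-feature, 3-factor loading matrix: a dominant walking-capacity factor
#' carried by the spatiotemporal and frequency features, a second factor on
#' the asymmetry features and a third on variability/regularity features —
#' mirroring the empirical structure in which one gait-speed-like component
#' dominates an IMU gait-feature battery.
#'
#' @return Numeric matrix (features x 3) with feature names as rownames.
#' @export
default_loadings <- function() {
  reg <- feature_registry()
  speedish <- c("gait_speed", "stride_time_mean", "step_time_mean",
                "stride_length_mean", "cadence", "stance_fraction",
                "swing_fraction",
                "dominant_freq_ap", "dominant_freq_v", "dominant_freq_ml",
                "dominant_amp_ap", "dominant_amp_v", "dominant_amp_ml",
                "harmonicity_index_v", "harmonic_ratio_ap",
                "harmonic_ratio_v")
  asym <- c("si_step_time", "si_stance_time", "si_swing_time",
            "ratio_step_time", "ratio_stance_time", "ratio_swing_time",
            "regularity_symmetry_ap")
  varb <- c("stride_time_sd", "stride_time_cv", "step_time_sd",
            "step_time_cv", "sample_entropy_ap", "sample_entropy_v",
            "stride_regularity_ap")
  feats <- c(speedish, asym, varb)
  stopifnot(all(feats %in% reg$name))
  L <- matrix(0, nrow = length(feats), ncol = 3,
              dimnames = list(feats, paste0("factor", 1:3)))
  L[speedish, 1] <- 0.9
  L[asym, 2] <- 0.8
  L[varb, 3] <- 0.8
  # mild cross-loadings: variability rises as capacity falls
  L[varb, 1] <- -0.2
  L
}
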
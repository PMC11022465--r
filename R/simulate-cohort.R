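#' Generate a synthetic longitudinal cohort with planted structure
#'
#' Draws a cohort of repeated subject-sessions in which (i) every gait
#' feature loads on a dominant latent walking-capacity factor (plus the
#' minor factors of the loading matrix) with additive noise, (ii) 2MWT gait
#' speed is a noisy affine function of the capacity factor, and (iii) the
#' daily-life outcomes (average/maximum gait speed, steps) are generated
#' from gait speed plus a subject-level random intercept, a planted
#' confounder path (a covariate correlated with capacity that also affects
#' the outcomes) and a planted speed-by-covariate interaction. The returned
#' truth record names the planted coefficients, so parameter-recovery and
#' selection-calibration tests can score against exact ground truth.
#'
#' @param spec a [cohort_spec()].
#' @return A list with
#'   \describe{
#'     \item{features}{data.frame: `measurement_id`, `subject`, `session`,
#'       `walking_aid`, then one column per feature (attribute
#'       `feature_cols` lists them).}
#'     \item{outcomes}{data.frame: ids plus `speed_2mwt`, `avg_speed`,
#'       `max_speed`, `steps`, and the candidate covariates
#'       `cand_confounder`, `cand_modifier`, `cand_null`.}
#'     \item{truth}{list of planted parameters: fixed slopes `beta` per
#'       outcome, subject intercept SDs `tau`, `confounder` /`modifier`
#'       /`null` candidate names and strengths, latent factor scores.}
#'   }
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 5,
#'                                    sessions_per_subject = 2))
#' dim(coh$features)
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("spec must be a cohort_spec", call. = FALSE)
  }
  ns <- spec$n_subjects
  k <- spec$sessions_per_subject
  n <- ns * k
  L <- spec$feature_loadings
  nf <- ncol(L)
  subj <- rep(seq_len(ns), each = k)
  sess <- rep(seq_len(k), times = ns)

  lat <- with_seed(child_seed(spec$seed, "latent"), {
    u <- rnorm(ns, 0, 0.8)                 # between-subject capacity
    w <- rnorm(n, 0, spec$latent_capacity_sd)
    f1 <- u[subj] + w
    others <- if (nf > 1) {
      sapply(seq_len(nf - 1), function(j) {
        uj <- rnorm(ns, 0, 0.5)
        uj[subj] + rnorm(n, 0, sqrt(1 - 0.25))
      })
    } else NULL
    cbind(f1, others)
  })

  feats <- with_seed(child_seed(spec$seed, "features"), {
    lat %*% t(L) + matrix(rnorm(n * nrow(L), 0, spec$feature_noise_sd),
                          nrow = n)
  })
  colnames(feats) <- rownames(L)

  out <- with_seed(child_seed(spec$seed, "outcomes"), {
    speed <- 0.7 + 0.25 * lat[, 1] + rnorm(n, 0, 0.03)
    conf <- 0.7 * lat[, 1] + rnorm(n, 0, 0.6)
    modf <- rnorm(n)
    null <- rnorm(n)
    tau <- c(avg_speed = 0.05, max_speed = 0.07, steps = 350)
    beta <- c(avg_speed = 0.3, max_speed = 0.45, steps = 2500)
    b_avg <- rnorm(ns, 0, tau["avg_speed"])[subj]
    b_max <- rnorm(ns, 0, tau["max_speed"])[subj]
    b_stp <- rnorm(ns, 0, tau["steps"])[subj]
    sc <- speed - 0.7
    planted <- spec$confounder_strength * conf +
      spec$modifier_strength * sc * modf
    avg <- 0.16 + beta["avg_speed"] * speed + planted + b_avg +
      rnorm(n, 0, spec$outcome_noise_sd)
    mx <- 0.32 + beta["max_speed"] * speed + 1.5 * planted + b_max +
      rnorm(n, 0, 1.5 * spec$outcome_noise_sd)
    steps <- round(550 + beta["steps"] * speed + 8000 * planted + b_stp +
                     rnorm(n, 0, 8000 * spec$outcome_noise_sd))
    list(speed = speed, conf = conf, modf = modf, null = null,
         avg = avg, mx = mx, steps = steps, beta = beta, tau = tau)
  })

  ids <- sprintf("m%03d", seq_len(n))
  features <- data.frame(measurement_id = ids, subject = factor(subj),
                         session = sess, walking_aid = FALSE,
                         stringsAsFactors = FALSE)
  features <- cbind(features, as.data.frame(feats))
  attr(features, "feature_cols") <- colnames(feats)

  outcomes <- data.frame(measurement_id = ids, subject = factor(subj),
                         session = sess,
                         speed_2mwt = out$speed,
                         avg_speed = out$avg, max_speed = out$mx,
                         steps = out$steps,
                         cand_confounder = out$conf,
                         cand_modifier = out$modf,
                         cand_null = out$null,
                         stringsAsFactors = FALSE)
  truth <- list(
    beta = out$beta, tau = out$tau,
    speed_model = c(intercept = 0.7, slope = 0.25, noise_sd = 0.03),
    confounder = "cand_confounder",
    confounder_strength = spec$confounder_strength,
    modifier = "cand_modifier",
    modifier_strength = spec$modifier_strength,
    null_candidate = "cand_null",
    latent = lat)
  list(features = features, outcomes = outcomes, truth = truth)
}
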
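# Linear mixed models: association between 2MWT gait speed and daily-life
# walking ability, forward selection of confounding / effect-modifying
# components, model comparison and residual diagnostics. Estimation by
# lme4 (REML for estimates; ML refits for AIC/BIC so fixed-effect
# structures are comparable).

#' Collinearity screen of components against gait speed
#'
#' Pearson correlation matrix over gait speed, the component scores and
#' the outcomes. A component whose absolute correlation with gait speed or
#' with an earlier-indexed component reaches the threshold is excluded
#' from candidacy; gait speed itself is never excluded.
#'
#' @param scores matrix/data.frame of component scores.
#' @param speed numeric gait-speed vector (same rows).
#' @param outcomes data.frame of outcome columns (same rows), optional.
#' @param threshold absolute-correlation exclusion threshold (default 0.9).
#' @return List with `correlation` (matrix), `excluded` (component names)
#'   and `kept`.
#' @export
correlation_screen <- function(scores, speed, outcomes = NULL,
                               threshold = 0.9) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    colnames(scores) <- sprintf("PC%d", seq_len(ncol(scores)) - 1)
  }
  vars <- cbind(gait_speed = speed, scores)
  if (!is.null(outcomes)) vars <- cbind(vars, as.matrix(outcomes))
  sds <- apply(vars, 2, sd)
  if (any(sds == 0)) {
    stop("undefined correlation, constant variable(s): ",
         paste(colnames(vars)[sds == 0], collapse = ", "), call. = FALSE)
  }
  cm <- cor(vars)
  excluded <- character(0)
  comp <- colnames(scores)
  for (i in seq_along(comp)) {
    earlier <- setdiff(comp[seq_len(i - 1)], excluded)
    against <- c("gait_speed", earlier)
    if (any(abs(cm[comp[i], against]) >= threshold)) {
      excluded <- c(excluded, comp[i])
    }
  }
  list(correlation = cm, excluded = excluded,
       kept = setdiff(comp, excluded))
}

.wald_fixed <- function(fit, conf = 0.95) {
  sm <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf) / 2)
  data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
             se = sm[, "Std. Error"],
             ci_lower = sm[, "Estimate"] - z * sm[, "Std. Error"],
             ci_upper = sm[, "Estimate"] + z * sm[, "Std. Error"],
             p = 2 * pnorm(-abs(sm[, "Estimate"] / sm[, "Std. Error"])),
             row.names = NULL)
}

#' Fit a random-intercept linear mixed model
#'
#' `outcome ~ fixed terms + (1 | subject)`, fitted by REML. AIC and BIC
#' are taken from a maximum-likelihood refit so models with different
#' fixed effects stay comparable. nRMSE is the root-mean-square
#' (conditional) residual divided by the observed outcome range
#' (`normalizer = "mean"` divides by the outcome mean instead).
#'
#' @param data data.frame with the outcome, predictors and subject column.
#' @param outcome outcome column name.
#' @param fixed character vector of fixed-effect terms (may include
#'   interaction terms like `"speed_2mwt:PC6"`).
#' @param subject grouping column name for the random intercept.
#' @param normalizer nRMSE normalizer, `"range"` (default) or `"mean"`.
#' @return An `lmm_fit`: `outcome`, `fixed` (coefficient table with SE,
#'   CI, Wald p), `subject_var`, `resid_var`, `aic`, `bic`, `nrmse`,
#'   `residuals`, `fitted`, `boundary` (singular-fit flag), `formula`,
#'   `n`, `model` (the lme4 fit), `data`.
#' @export
fit_lmm <- function(data, outcome, fixed, subject = "subject",
                    normalizer = c("range", "mean")) {
  normalizer <- match.arg(normalizer)
  need <- unique(c(outcome, subject,
                   unlist(strsplit(fixed, ":", fixed = TRUE))))
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- complete.cases(data[, need])
  d <- data[rows, , drop = FALSE]
  if (length(unique(d[[subject]])) < 2) {
    stop("need >= 2 subjects", call. = FALSE)
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(fixed, collapse = " + "),
                                 "+ (1 |", subject, ")"))
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  mixed_path <- function() {
    fit <- lme4::lmer(fml, data = d, REML = TRUE, control = ctrl)
    fit_ml <- suppressWarnings(suppressMessages(lme4::refitML(fit)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    res <- resid(fit)
    nr <- sqrt(mean(res^2))
    fx <- .wald_fixed(fit)
    if (anyNA(fx$se)) stop("degenerate vcov")
    structure(list(outcome = outcome, fixed = fx,
                   subject_var = vc$vcov[vc$grp == subject],
                   resid_var = vc$vcov[vc$grp == "Residual"],
                   aic = stats::AIC(fit_ml), bic = stats::BIC(fit_ml),
                   nrmse = nr / switch(normalizer,
                                       range = diff(range(d[[outcome]])),
                                       mean = mean(d[[outcome]])),
                   residuals = as.numeric(res),
                   fitted = as.numeric(stats::fitted(fit)),
                   boundary = lme4::isSingular(fit),
                   formula = deparse(fml), n = nrow(d),
                   rows = which(rows), model = fit, data = d),
              class = "lmm_fit")
  }
  out <- tryCatch(suppressWarnings(mixed_path()), error = function(e) NULL)
  if (is.null(out)) {
    # degenerate data (e.g. an exactly deterministic outcome) can break the
    # mixed-model optimizer; report the fixed-effects fit with the subject
    # variance pinned at zero and the boundary flag set
    fml_fe <- stats::as.formula(paste(outcome, "~",
                                      paste(fixed, collapse = " + ")))
    fe <- lm(fml_fe, data = d)
    res_fe <- as.numeric(resid(fe))
    nr_fe <- sqrt(mean(res_fe^2))
    nrmse_fe <- nr_fe / switch(normalizer,
                               range = diff(range(d[[outcome]])),
                               mean = mean(d[[outcome]]))
    return(structure(list(outcome = outcome, fixed = .wald_fixed(fe),
                          subject_var = 0,
                          resid_var = sum(res_fe^2) / fe$df.residual,
                          aic = stats::AIC(fe), bic = stats::BIC(fe),
                          nrmse = nrmse_fe, residuals = res_fe,
                          fitted = as.numeric(stats::fitted(fe)),
                          boundary = TRUE, formula = deparse(fml),
                          n = nrow(d), rows = which(rows), model = fe,
                          data = d), class = "lmm_fit"))
  }
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s, n = %d%s\n", x$formula, x$n,
              if (x$boundary) " [boundary: zero subject variance]" else ""))
  print(x$fixed, digits = 3)
  cat(sprintf("  nRMSE %.3f  AIC %.1f  BIC %.1f\n", x$nrmse, x$aic, x$bic))
  invisible(x)
}

#' Gait-speed-only base model
#'
#' @param data data.frame with outcome, speed and subject columns.
#' @param outcome outcome column name.
#' @param speed gait-speed column name.
#' @param subject subject column name.
#' @param ... passed to [fit_lmm()].
#' @return An `lmm_fit`.
#' @export
fit_base <- function(data, outcome, speed = "speed_2mwt",
                     subject = "subject", ...) {
  fit_lmm(data, outcome, fixed = speed, subject = subject, ...)
}

#' Forward selection of confounders and effect modifiers
#'
#' Candidates are visited in the given order (descending explained
#' variance when scores come from a PCA). For each candidate the working
#' model is refitted with the candidate as a main effect; it is flagged a
#' confounder when the gait-speed coefficient changes by at least
#' `change_threshold` (10%) relative to the base gait-speed-only model
#' (`reference = "sequential"` compares to the accumulating model
#' instead). A second refit adds the speed-by-candidate interaction
#' (maximum likelihood; Wald test); the candidate is an effect modifier
#' when the interaction p-value is below `alpha`. A candidate flagged
#' either way is retained in the working model. The definitive model
#' contains gait speed and every retained candidate (plus interactions
#' for modifiers).
#'
#' @param base an `lmm_fit` from [fit_base()].
#' @param candidates character vector of candidate column names in
#'   `base$data` order of visitation, or a matrix of scores whose columns
#'   are appended to the data.
#' @param change_threshold relative change marking a confounder.
#' @param alpha significance level for the interaction.
#' @param reference `"base"` or `"sequential"` confounding reference.
#' @return List with `fit` (definitive `lmm_fit`) and `trace` (a
#'   `selection_trace` data.frame: candidate, `delta_pct`, `confounder`,
#'   `interaction_p`, `modifier`, `included`, `note`).
#' @export
forward_select <- function(base, candidates, change_threshold = 0.10,
                           alpha = 0.05, reference = c("base", "sequential")) {
  reference <- match.arg(reference)
  stopifnot(inherits(base, "lmm_fit"))
  d <- base$data
  speed <- base$fixed$term[2]
  if (is.matrix(candidates) || is.data.frame(candidates)) {
    sc <- as.data.frame(candidates)
    if (nrow(sc) != nrow(d)) {
      stop("candidate scores must align with the base-model rows",
           call. = FALSE)
    }
    d <- cbind(d, sc)
    candidates <- colnames(sc)
  }
  beta_base <- base$fixed$estimate[base$fixed$term == speed]
  working <- speed
  ref_beta <- beta_base
  trace <- NULL
  for (cand in candidates) {
    row <- data.frame(candidate = cand, delta_pct = NA_real_,
                      confounder = FALSE, interaction_p = NA_real_,
                      modifier = FALSE, included = FALSE, note = "")
    # candidate evaluated against the reference model: the gait-speed-only
    # base model (default) or the accumulating working model
    eval_fixed <- if (reference == "base") speed else working
    main <- tryCatch(
      fit_lmm(d, base$outcome, fixed = c(eval_fixed, cand)),
      error = function(e) NULL)
    inter <- tryCatch(
      fit_lmm(d, base$outcome,
              fixed = c(eval_fixed, cand, paste0(speed, ":", cand))),
      error = function(e) NULL)
    if (is.null(main) || is.null(inter)) {
      row$note <- "indeterminate: fit failed"
      trace <- rbind(trace, row)
      next
    }
    beta <- main$fixed$estimate[main$fixed$term == speed]
    row$delta_pct <- 100 * abs(beta - ref_beta) / abs(ref_beta)
    row$confounder <- row$delta_pct >= 100 * change_threshold
    ip <- inter$fixed$p[inter$fixed$term == paste0(speed, ":", cand)]
    row$interaction_p <- ip
    row$modifier <- is.finite(ip) && ip < alpha
    row$included <- row$confounder || row$modifier
    if (row$included) {
      working <- c(working, cand)
      if (row$modifier) working <- c(working, paste0(speed, ":", cand))
      if (reference == "sequential") {
        wf <- fit_lmm(d, base$outcome, fixed = working)
        ref_beta <- wf$fixed$estimate[wf$fixed$term == speed]
      }
    }
    trace <- rbind(trace, row)
  }
  definitive <- fit_lmm(d, base$outcome, fixed = working)
  class(trace) <- c("selection_trace", "data.frame")
  list(fit = definitive, trace = trace)
}

#' Compare fitted models on identical rows
#'
#' nRMSE, AIC and BIC per model; AIC/BIC come from maximum-likelihood
#' refits since REML likelihoods are not comparable across fixed-effect
#' structures (recorded in the output).
#'
#' @param base,definitive `lmm_fit` objects on identical rows.
#' @param pc_only optional third `lmm_fit` (components-only model).
#' @return A data.frame with one row per model.
#' @export
compare_models <- function(base, definitive, pc_only = NULL) {
  fits <- list(gait_speed_only = base, definitive = definitive)
  if (!is.null(pc_only)) fits$pc_only <- pc_only
  rows <- lapply(fits, function(f) f$rows)
  if (length(unique(vapply(rows, paste, "", collapse = ","))) != 1) {
    stop("invalid comparison: models were fitted on different rows",
         call. = FALSE)
  }
  out <- data.frame(model = names(fits),
                    nrmse = vapply(fits, `[[`, 0, "nrmse"),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    bic = vapply(fits, `[[`, 0, "bic"),
                    row.names = NULL)
  attr(out, "likelihood") <- "ML refits (REML not comparable across fixed effects)"
  out
}

#' Residual diagnostics of a mixed-model fit
#'
#' Skewness, excess kurtosis, a Shapiro-Wilk normality test and a
#' heteroscedasticity screen (slope of |residual| on fitted values), with
#' pass/fail flags at `alpha`.
#'
#' @param fit an `lmm_fit`.
#' @param alpha flag level.
#' @return List with the statistics, p-values and `normal` /
#'   `homoscedastic` / `degenerate` flags.
#' @export
diagnostics <- function(fit, alpha = 0.05) {
  r <- fit$residuals
  if (sd(r) < 1e-12) {
    return(list(skewness = NA_real_, kurtosis_excess = NA_real_,
                shapiro_p = NA_real_, het_slope = NA_real_,
                het_p = NA_real_, normal = NA, homoscedastic = NA,
                degenerate = TRUE))
  }
  z <- (r - mean(r)) / sd(r)
  skew <- mean(z^3)
  kurt <- mean(z^4) - 3
  sw <- stats::shapiro.test(if (length(r) > 5000) sample(r, 5000) else r)
  hl <- lm(abs(r) ~ fit$fitted)
  hsm <- summary(hl)$coefficients
  het_p <- hsm[2, 4]
  list(skewness = skew, kurtosis_excess = kurt, shapiro_p = sw$p.value,
       het_slope = hsm[2, 1], het_p = het_p,
       normal = sw$p.value >= alpha, homoscedastic = het_p >= alpha,
       degenerate = FALSE)
}
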
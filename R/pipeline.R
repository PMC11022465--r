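#' Run the full statistical pipeline on a cohort
#'
#' From a longitudinal feature table and outcome table: correlation
#' pruning, KMO adequacy, z-scoring, PCA with Kaiser retention and
#' labelling, collinearity screen of component scores against 2MWT gait
#' speed, then per walking-ability outcome a gait-speed-only mixed model,
#' forward selection of confounding / effect-modifying components, model
#' comparison and residual diagnostics.
#'
#' @param features feature table (metadata + feature columns).
#' @param outcomes outcome table aligned by `measurement_id`, with
#'   `speed_2mwt`, the outcome columns and `subject`.
#' @param outcome_names outcomes to model.
#' @param prune_threshold correlation-pruning threshold.
#' @param screen_threshold collinearity-screen threshold.
#' @return A `pipeline_result` list: `selection` (pruning report), `kmo`,
#'   `pca` (labeled model), `scores`, `screen`, and `models` — per outcome
#'   a list with `base`, `definitive`, `trace`, `comparison`,
#'   `diagnostics`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 12, seed = 4))
#' res <- run_pipeline(coh$features, coh$outcomes,
#'                     outcome_names = "avg_speed")
#' res$models$avg_speed$comparison
run_pipeline <- function(features, outcomes,
                         outcome_names = c("avg_speed", "max_speed",
                                           "steps"),
                         prune_threshold = 0.95, screen_threshold = 0.9) {
  pr <- prune_correlated(features, threshold = prune_threshold)
  adequacy <- kmo(pr$table)
  zt <- standardize(pr$table)
  model <- fit_pca(zt)
  model <- label_components(model, zt)
  scores <- project(model, pr$table)
  stopifnot(identical(features$measurement_id, outcomes$measurement_id))
  screen <- correlation_screen(scores, outcomes$speed_2mwt,
                               threshold = screen_threshold)
  d <- cbind(outcomes, as.data.frame(scores))
  models <- list()
  for (oc in outcome_names) {
    base <- fit_base(d, oc)
    sel <- forward_select(base, screen$kept)
    pc_only <- fit_lmm(d, oc, fixed = screen$kept)
    models[[oc]] <- list(
      base = base, definitive = sel$fit, trace = sel$trace,
      comparison = compare_models(base, sel$fit, pc_only),
      diagnostics = diagnostics(sel$fit))
  }
  structure(list(selection = pr$report, kmo = adequacy, pca = model,
                 scores = scores, screen = screen, models = models),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  pruned %d feature(s); overall KMO %.2f\n",
              nrow(x$selection$dropped), x$kmo$overall))
  cat(sprintf("  PCA: %d component(s), %.1f%% variance\n", x$pca$retained,
              100 * sum(x$pca$explained[seq_len(x$pca$retained)])))
  for (oc in names(x$models)) {
    m <- x$models[[oc]]
    kept <- m$trace$candidate[m$trace$included]
    cat(sprintf("  %s: definitive model keeps {%s}\n", oc,
                paste(kept, collapse = ", ")))
  }
  invisible(x)
}
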
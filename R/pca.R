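#' Fit a PCA with Kaiser retention on z-scored features
#'
#' Eigendecomposition of the feature correlation matrix (identical to the
#' covariance of z-scores). Components with eigenvalue > 1 are retained
#' (Kaiser criterion). Deterministic sign convention: each loading column
#' is oriented so its largest-magnitude entry is positive. Eigenvalues in
#' `[0.95, 1.05]` are flagged near-threshold since retention is unstable
#' there.
#'
#' @param ztable a `standardized_table` from [standardize()].
#' @return A `pca_model`: `loadings` (features x retained components,
#'   orthonormal columns), `eigenvalues` (all, non-increasing),
#'   `explained` (fractions over ALL components, summing to 1),
#'   `retained`, `near_threshold`, `center`, `scale`, `labels`
#'   (filled by [label_components()]).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 10))
#' m <- fit_pca(standardize(coh$features))
#' m$retained
fit_pca <- function(ztable) {
  cols <- feature_cols(ztable)
  z <- as.matrix(ztable[, cols, drop = FALSE])
  if (anyNA(z)) stop("missing values in features", call. = FALSE)
  R <- cor(z)
  e <- eigen(R, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  retained <- which(ev > 1)
  if (nrow(z) <= length(retained)) {
    stop("need more rows than retained components", call. = FALSE)
  }
  V <- e$vectors[, retained, drop = FALSE]
  # sign convention: largest-magnitude entry of each column positive
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- cols
  colnames(V) <- sprintf("PC%d", seq_len(ncol(V)) - 1)
  structure(list(
    loadings = V,
    eigenvalues = ev,
    explained = ev / sum(ev),
    retained = length(retained),
    near_threshold = which(ev >= 0.95 & ev <= 1.05),
    center = attr(ztable, "center"),
    scale = attr(ztable, "scale"),
    sign_convention = "largest-magnitude loading positive",
    tie_break = "registry order",
    labels = NULL), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d/%d components retained (eigenvalue > 1), %s%% variance\n",
              x$retained, length(x$eigenvalues),
              round(100 * sum(x$explained[seq_len(x$retained)]), 1)))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Project data onto a fitted PCA
#'
#' Standardizes with the model's *stored* means and SDs (no refitting) and
#' multiplies by the loading matrix.
#'
#' @param model a `pca_model`.
#' @param table feature table containing every model feature.
#' @return Matrix of component scores (rows x retained components).
#' @export
project <- function(model, table) {
  cols <- rownames(model$loadings)
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop("schema error, missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(table[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  z <- sweep(sweep(m, 2, model$center[cols]), 2, model$scale[cols], "/")
  z %*% model$loadings
}

#' Label retained components by their best-correlated feature
#'
#' Each component is named after the feature whose Pearson correlation
#' with the component scores has the largest absolute value; ties are
#' broken by registry order and recorded.
#'
#' @param model a `pca_model`.
#' @param ztable the fitting `standardized_table`.
#' @return The model with `labels` (named by component) and `label_ties`.
#' @export
label_components <- function(model, ztable) {
  cols <- rownames(model$loadings)
  z <- as.matrix(ztable[, cols, drop = FALSE])
  scores <- z %*% model$loadings  # ztable is already standardized
  labels <- character(ncol(scores))
  ties <- vector("list", ncol(scores))
  for (j in seq_len(ncol(scores))) {
    r <- abs(as.numeric(cor(z, scores[, j])))
    r[!is.finite(r)] <- -Inf
    best <- which(r >= max(r) - 1e-12)
    labels[j] <- cols[best[1]]  # registry order tie-break
    if (length(best) > 1) ties[[j]] <- cols[best]
  }
  names(labels) <- colnames(model$loadings)
  model$labels <- labels
  model$label_ties <- ties
  model
}

#' Serialize / restore a PCA model as structured text
#'
#' Stores means, SDs, loadings, eigenvalues, labels and conventions in a
#' YAML file so projections are reproducible bit-for-bit.
#'
#' @param model a `pca_model`.
#' @param path file path.
#' @return `write_pca_model` returns `path` invisibly; `read_pca_model`
#'   the restored model.
#' @export
write_pca_model <- function(model, path) {
  obj <- list(features = rownames(model$loadings),
              components = colnames(model$loadings),
              center = as.list(model$center),
              scale = as.list(model$scale),
              loadings = apply(model$loadings, 2, as.list, simplify = FALSE),
              eigenvalues = model$eigenvalues,
              retained = model$retained,
              labels = as.list(model$labels),
              sign_convention = model$sign_convention,
              tie_break = model$tie_break)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- yaml::read_yaml(path)
  L <- sapply(obj$loadings, function(col) unlist(col))
  rownames(L) <- obj$features
  colnames(L) <- obj$components
  ev <- unlist(obj$eigenvalues)
  structure(list(loadings = L, eigenvalues = ev,
                 explained = ev / sum(ev), retained = obj$retained,
                 near_threshold = which(ev >= 0.95 & ev <= 1.05),
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 sign_convention = obj$sign_convention,
                 tie_break = obj$tie_break,
                 labels = unlist(obj$labels)), class = "pca_model")
}
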
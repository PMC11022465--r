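# Feature selection: correlation pruning, Kaiser-Meyer-Olkin sampling
# adequacy, z-scoring. Tables are data.frames whose non-feature columns
# (ids, metadata) are listed in .meta_cols.

.meta_cols <- c("measurement_id", "subject", "session", "walking_aid")

#' Feature columns of a table
#' @param table a feature table (data.frame).
#' @return Character vector of feature column names (the `feature_cols`
#'   attribute when present, else all non-metadata columns).
#' @export
feature_cols <- function(table) {
  fc <- attr(table, "feature_cols")
  if (!is.null(fc)) return(intersect(fc, names(table)))
  setdiff(names(table), .meta_cols)
}

.feature_matrix <- function(table, cols = feature_cols(table)) {
  m <- as.matrix(table[, cols, drop = FALSE])
  if (anyNA(m)) {
    bad <- cols[colSums(is.na(table[, cols, drop = FALSE])) > 0]
    stop("missing values in: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Prune near-identical features by pairwise correlation
#'
#' While any pair of features has `|r|` above the threshold the two are
#' considered identical and, among all features involved in violating
#' pairs, the one with the largest summed absolute correlation to all
#' current features is dropped; correlations are recomputed after every
#' single drop. Ties are broken by registry (column) order. Absolute
#' correlation is used, so sign-flipped duplicates are also pruned.
#'
#' @param table feature table (>= 2 features, >= 3 rows, complete).
#' @param threshold correlation threshold (default 0.95).
#' @return List with `table` (pruned) and `report` (a `selection_report`:
#'   `dropped` data.frame of name/reason/summed correlation, `surviving`).
#' @export
#' @examples
#' d <- data.frame(a = c(1, 2, 3, 5), b = c(1, 2, 3, 5) * 2,
#'                 c = c(4, 1, 3, 2))
#' prune_correlated(d)$report$dropped
prune_correlated <- function(table, threshold = 0.95) {
  cols <- feature_cols(table)
  if (length(cols) < 2 || nrow(table) < 3) {
    stop("need >= 2 features and >= 3 rows", call. = FALSE)
  }
  m <- .feature_matrix(table, cols)
  dropped <- data.frame(name = character(0), reason = character(0),
                        summed_abs_r = numeric(0))
  repeat {
    r <- abs(cor(m))
    diag(r) <- 0
    if (max(r) <= threshold) break
    viol <- unique(as.vector(which(r > threshold, arr.ind = TRUE)))
    sums <- rowSums(abs(cor(m)))  # includes the diagonal 1 for everyone
    cand <- viol[order(-sums[viol], viol)][1]  # tie-break: column order
    dropped <- rbind(dropped,
                     data.frame(name = colnames(m)[cand],
                                reason = sprintf("corr_gt_%g", threshold),
                                summed_abs_r = sums[cand] - 1))
    m <- m[, -cand, drop = FALSE]
    if (ncol(m) < 2) break
  }
  surviving <- colnames(m)
  out <- table[, c(intersect(names(table), .meta_cols), surviving)]
  attr(out, "feature_cols") <- surviving
  report <- structure(list(dropped = dropped, surviving = surviving,
                           threshold = threshold,
                           correlation = "absolute"),
                      class = "selection_report")
  list(table = out, report = report)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares raw correlations with anti-image partial correlations:
#' `KMO_j = sum r^2 / (sum r^2 + sum p^2)` over the off-diagonal pairs
#' involving feature j, and the overall KMO sums over all off-diagonal
#' pairs. Partial correlations come from the inverse correlation matrix;
#' if that matrix is numerically singular a small ridge (1e-8) is added
#' and recorded. Overall KMO below 0.7 or a per-feature KMO below 0.5 is
#' flagged as inadequate.
#'
#' @param table feature table (complete, >= 2 features).
#' @return List `overall`, `per_feature` (named), `flags`
#'   (`overall_below_0.7`, `features_below_0.5`), `ridge_added`,
#'   `degenerate` (TRUE when all off-diagonal correlations vanish and the
#'   measure is 0/0), `underdetermined` (fewer rows than features).
#' @export
kmo <- function(table) {
  m <- .feature_matrix(table)
  R <- cor(m)
  p <- ncol(R)
  ridge <- FALSE
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv) || !all(is.finite(Rinv))) {
    Rinv <- solve(R + diag(1e-8, p))
    ridge <- TRUE
  }
  # anti-image partial correlations
  d <- 1 / sqrt(diag(Rinv))
  P <- -Rinv * outer(d, d)
  diag(P) <- 0
  R0 <- R
  diag(R0) <- 0
  r2 <- R0^2
  p2 <- P^2
  denom_j <- colSums(r2) + colSums(p2)
  per <- ifelse(denom_j > 1e-10, colSums(r2) / denom_j, NA_real_)
  names(per) <- colnames(m)
  denom <- sum(r2) + sum(p2)
  overall <- if (denom > 1e-10) sum(r2) / denom else NA_real_
  structure(list(
    overall = overall,
    per_feature = per,
    flags = list(overall_below_0.7 = isTRUE(overall < 0.7),
                 features_below_0.5 = names(per)[!is.na(per) & per < 0.5]),
    ridge_added = ridge,
    degenerate = denom < 1e-10 || anyNA(per),
    underdetermined = nrow(m) < p), class = "kmo_report")
}

#' Z-score a feature table
#'
#' Column-wise `(x - mean) / SD` with the sample SD (n - 1 denominator).
#' The fitted means and SDs are stored so held-out data can be transformed
#' with the *fitting* parameters via [apply_standardization()].
#'
#' @param table feature table with all feature SDs > 0.
#' @return A `standardized_table`: the z-scored table with attributes
#'   `center` and `scale`.
#' @export
standardize <- function(table) {
  cols <- feature_cols(table)
  m <- .feature_matrix(table, cols)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  if (any(sdv == 0)) {
    stop("constant feature(s): ", paste(cols[sdv == 0], collapse = ", "),
         call. = FALSE)
  }
  z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  out <- table
  out[, cols] <- z
  attr(out, "feature_cols") <- cols
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  class(out) <- c("standardized_table", class(table))
  out
}

#' @rdname standardize
#' @param fitted a `standardized_table` (or anything carrying `center` /
#'   `scale` attributes).
#' @param newdata feature table containing at least the fitted features.
#' @export
apply_standardization <- function(fitted, newdata) {
  mu <- attr(fitted, "center")
  sdv <- attr(fitted, "scale")
  cols <- names(mu)
  missing <- setdiff(cols, names(newdata))
  if (length(missing)) {
    stop("schema error, missing feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- .feature_matrix(newdata, cols)
  z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  out <- newdata
  out[, cols] <- z
  attr(out, "feature_cols") <- cols
  out
}

#' Write / read a feature table as delimited text
#' @param table data.frame with metadata and feature columns.
#' @param path file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` the table with its `feature_cols` attribute set.
#' @export
write_feature_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  attr(df, "feature_cols") <- setdiff(names(df), .meta_cols)
  df
}
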
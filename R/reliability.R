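# Test-retest reliability panel: ICC(2,1) with F-based confidence
# interval, SEM, MDC and RMSE per component.

# two-way random effects, absolute agreement, single measure, from the
# two-way ANOVA mean squares (k sessions, n subjects)
.icc21 <- function(test, retest, conf = 0.95) {
  n <- length(test)
  k <- 2
  y <- c(test, retest)
  subj <- factor(rep(seq_len(n), 2))
  sess <- factor(rep(1:2, each = n))
  ms <- anova(lm(y ~ subj + sess))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # F-based CI (McGraw & Wong, agreement, single rater)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - conf
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  if (!is.finite(lo)) lo <- NA_real_
  if (!is.finite(hi)) hi <- NA_real_
  list(icc = icc, lower = lo, upper = hi,
       msr = msr, msc = msc, mse = mse)
}

.icc_band <- function(icc) {
  if (!is.finite(icc)) return(NA_character_)
  if (icc > 0.9) "excellent"
  else if (icc >= 0.75) "good"
  else if (icc >= 0.5) "moderate"
  else "poor"
}

#' Test-retest reliability panel per component
#'
#' For each column of paired test/retest scores: ICC(2,1) (two-way
#' random-effects, absolute-agreement, single-measure) with its F-based
#' 95% confidence interval, the standard error of measurement
#' `SEM = pooled SD x sqrt(1 - ICC)`, the minimal detectable change
#' `MDC = 1.96 x sqrt(2) x SEM`, the test-retest RMSE, and a qualitative
#' band (poor < 0.5 <= moderate < 0.75 <= good <= 0.9 < excellent).
#'
#' @param test matrix (or vector) of session-1 scores, subjects in rows.
#' @param retest matching session-2 scores.
#' @param conf confidence level for the ICC interval.
#' @return A `reliability_report` data.frame with one row per component:
#'   `component`, `icc`, `icc_lower`, `icc_upper`, `sem`, `mdc`, `rmse`,
#'   `band`.
#' @export
#' @examples
#' r <- reliability(cbind(pc = c(1, 2, 3, 4)),
#'                  cbind(pc = c(1.1, 2.1, 2.9, 4.0)))
#' r$icc
reliability <- function(test, retest, conf = 0.95) {
  if (is.null(dim(test))) test <- cbind(score = test)
  if (is.null(dim(retest))) retest <- cbind(score = retest)
  if (!all(dim(test) == dim(retest))) {
    stop("test and retest must have matching dimensions", call. = FALSE)
  }
  if (nrow(test) < 2) {
    stop("insufficient pairs: need >= 2 complete pairs", call. = FALSE)
  }
  cn <- colnames(test)
  if (is.null(cn)) cn <- sprintf("PC%d", seq_len(ncol(test)) - 1)
  rows <- lapply(seq_len(ncol(test)), function(j) {
    x <- test[, j]; y <- retest[, j]
    ok <- complete.cases(x, y)
    if (sum(ok) < 2) {
      stop("insufficient pairs for component ", cn[j], call. = FALSE)
    }
    x <- x[ok]; y <- y[ok]
    if (sd(c(x, y)) == 0 || all(x == y)) {
      # perfect agreement (or no variance at all): agreement is exact
      icc <- if (sd(c(x, y)) == 0) NA_real_ else 1
      i <- list(icc = 1, lower = NA_real_, upper = NA_real_)
      if (sd(c(x, y)) == 0) i$icc <- NA_real_
      sem <- 0
    } else {
      i <- .icc21(x, y, conf)
      sem <- sd(c(x, y)) * sqrt(max(0, 1 - i$icc))
    }
    rmse <- sqrt(mean((x - y)^2))
    data.frame(component = cn[j], icc = i$icc, icc_lower = i$lower,
               icc_upper = i$upper, sem = sem,
               mdc = 1.96 * sqrt(2) * sem, rmse = rmse,
               band = .icc_band(i$icc))
  })
  structure(do.call(rbind, rows),
            class = c("reliability_report", "data.frame"))
}
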
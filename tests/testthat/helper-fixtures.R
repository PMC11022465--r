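# Shared fixtures, built in code. Kept small so the suite stays fast.

# short 2MWT at defaults, reused across files
fixture_2mwt <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_2mwt_signals(
        gait_truth(stride_time = 1.2, gait_speed = 0.8),
        duration = 60, rate = 104, noise_sd = 0.1, seed = 42)
    }
    cache
  }
})

# random feature table with n rows and p features
random_table <- function(n, p, seed) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    df <- as.data.frame(m)
    names(df) <- sprintf("f%02d", seq_len(p))
    df
  })
}

# rank-1 plus noise table (single dominant factor)
factor_table <- function(n, p, noise_sd, seed) {
  withr::with_seed(seed, {
    lat <- rnorm(n)
    m <- outer(lat, rep(1, p)) + matrix(rnorm(n * p, 0, noise_sd), n, p)
    df <- as.data.frame(m)
    names(df) <- sprintf("f%02d", seq_len(p))
    df
  })
}

# brute-force partial correlation of columns i and j given all others,
# via residuals of ordinary regressions (independent of the matrix-inverse
# route used by kmo())
partial_cor_bruteforce <- function(m, i, j) {
  others <- setdiff(seq_len(ncol(m)), c(i, j))
  if (!length(others)) return(cor(m[, i], m[, j]))
  ri <- resid(lm(m[, i] ~ m[, others]))
  rj <- resid(lm(m[, j] ~ m[, others]))
  cor(ri, rj)
}

# brute-force KMO from explicit pairwise sums
kmo_bruteforce <- function(m) {
  m <- as.matrix(m)
  p <- ncol(m)
  R <- cor(m)
  P <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      P[i, j] <- P[j, i] <- partial_cor_bruteforce(m, i, j)
    }
  }
  diag(R) <- 0
  r2 <- R^2; p2 <- P^2
  list(overall = sum(r2) / (sum(r2) + sum(p2)),
       per_feature = colSums(r2) / (colSums(r2) + colSums(p2)))
}

# brute-force two-way ANOVA mean squares and ICC(2,1) from explicit sums
icc21_bruteforce <- function(test, retest) {
  y <- cbind(test, retest)
  n <- nrow(y); k <- 2
  gm <- mean(y)
  rm_ <- rowMeans(y); cm <- colMeans(y)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
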
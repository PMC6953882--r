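# Independent brute-force oracles for the mixed-model scan.

# Per-SNP restricted-likelihood grid oracle: for each SNP, the variance
# ratio delta = se2/sg2 is chosen by exhaustive grid search maximizing the
# REML criterion of the model including that SNP, followed by a Wald t-test
# from dense GLS algebra.  Exercises the full likelihood per SNP, unlike
# the P3D scan which fixes delta from the null model.
oracle_lmm_persnp <- function(y, x, ek, grid = seq(-6, 8, by = 0.05)) {
  n <- length(y)
  U <- ek$vectors
  lam <- pmax(ek$values, 1e-8)
  ys <- crossprod(U, y)[, 1]
  Xs <- crossprod(U, cbind(1, x))
  best <- -Inf; bp <- NA_real_
  for (ld in grid) {
    v <- lam + 10^ld
    W <- Xs / v
    XtX <- crossprod(Xs, W)
    b <- solve(XtX, crossprod(W, ys))
    rss <- sum((ys - Xs %*% b)^2 / v)
    ll <- -0.5 * ((n - 2) * log(rss) + sum(log(v)) +
                    as.numeric(determinant(XtX)$modulus))
    if (ll > best) {
      best <- ll
      se <- sqrt(rss / (n - 2) * solve(XtX)[2, 2])
      bp <- 2 * stats::pt(-abs(b[2] / se), n - 2)
    }
  }
  bp
}

# Brute-force grid/GLS oracle of the P3D scan itself: the null-model REML
# delta is found by exhaustive grid search (no optimizer), then every SNP
# is tested by dense weighted least squares -- an independent
# implementation path for the same estimand as lmm_scan().
oracle_lmm_p3d <- function(y, G, ek, grid = seq(-6, 8, by = 0.01)) {
  n <- length(y)
  U <- ek$vectors
  lam <- pmax(ek$values, 1e-8)
  ys <- crossprod(U, y)[, 1]
  ones <- crossprod(U, rep(1, n))[, 1]
  best <- -Inf; bd <- Inf
  for (ld in grid) {
    v <- lam + 10^ld
    sxx <- sum(ones^2 / v)
    b <- sum(ones * ys / v) / sxx
    rss <- sum((ys - ones * b)^2 / v)
    ll <- -0.5 * ((n - 1) * log(rss) + sum(log(v)) + log(sxx))
    if (ll > best) { best <- ll; bd <- 10^ld }
  }
  # boundary preference mirrors the scan's "no genetic variance" rule
  v8 <- lam + 10^max(grid)
  sxx <- sum(ones^2 / v8); b <- sum(ones * ys / v8) / sxx
  ll8 <- -0.5 * ((n - 1) * log(sum((ys - ones * b)^2 / v8)) +
                   sum(log(v8)) + log(sxx))
  if (ll8 >= best - 1e-6) bd <- 10^max(grid)
  vapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    v <- lam + bd
    Xs <- cbind(ones, crossprod(U, x)[, 1])
    W <- Xs / v
    XtX <- crossprod(Xs, W)
    b2 <- solve(XtX, crossprod(W, ys))
    rss <- sum((ys - Xs %*% b2)^2 / v)
    se <- sqrt(rss / (n - 2) * solve(XtX)[2, 2])
    2 * stats::pt(-abs(b2[2] / se), n - 2)
  }, 0)
}
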
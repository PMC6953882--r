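#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the fraction of SNPs at which lines i and j carry identical
#' alleles (haploid coding), with missing genotypes excluded pairwise.
#' Used as the covariance structure of the polygenic random effect in
#' [lmm_scan()].
#'
#' @param genotypes A `geno_matrix` or a lines x SNPs 0/1 matrix (may
#'   contain `NA`).
#' @return Symmetric n x n matrix, diagonal 1, entries in `[0, 1]`.
#' @export
ibs_kinship <- function(genotypes) {
  G <- if (inherits(genotypes, "geno_matrix")) genotypes$G else genotypes
  if (nrow(G) < 2 || ncol(G) < 1) stop("need >= 2 lines and >= 1 SNP")
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0
  H0 <- (1 - G); H0[!M] <- 0
  shared <- tcrossprod(G0) + tcrossprod(H0)
  denom <- tcrossprod(M * 1)
  if (any(denom == 0))
    stop("line pair(s) with zero jointly-called SNPs")
  K <- shared / denom
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

#' Minor-allele-frequency filter
#'
#' Retains SNPs with MAF strictly greater than `threshold` (so a SNP at
#' exactly the threshold, or a monomorphic SNP, is removed).
#'
#' @param genotypes A `geno_matrix`.
#' @param threshold MAF threshold in (0, 0.5); default 0.05.
#' @return The filtered `geno_matrix`.
#' @export
maf_filter <- function(genotypes, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 0.5)
  f <- colMeans(genotypes$G, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  keep <- maf > threshold
  new_geno_matrix(genotypes$G[, keep, drop = FALSE],
                  genotypes$map[keep, , drop = FALSE])
}

## REML fit of y = mu + u + e, cov(u) = sg2 * K, via the eigendecomposition
## of K; delta = se2 / sg2 profiled on a log scale.  If the likelihood gain
## over the delta -> Inf boundary (sg2 = 0) is negligible, the boundary fit
## is reported, which downstream code treats as "no genetic variance".
reml_null <- function(y, eig, tol = 1e-6) {
  n <- length(y)
  ys <- crossprod(eig$vectors, y)[, 1]
  xs <- crossprod(eig$vectors, rep(1, n))[, 1]
  lam <- eig$values
  crit <- function(log10d) {
    d <- 10^log10d
    v <- lam + d
    sxx <- sum(xs^2 / v)
    b <- sum(xs * ys / v) / sxx
    rss <- sum((ys - xs * b)^2 / v)
    -0.5 * ((n - 1) * log(rss) + sum(log(v)) + log(sxx))
  }
  opt <- stats::optimize(crit, c(-6, 8), maximum = TRUE, tol = 1e-4)
  at_boundary <- crit(8) >= opt$objective - tol
  if (at_boundary)
    return(list(delta = Inf, sg2 = 0, se2 = stats::var(y), mu = mean(y),
                boundary = TRUE))
  delta <- 10^opt$maximum
  v <- lam + delta
  sxx <- sum(xs^2 / v)
  b <- sum(xs * ys / v) / sxx
  sg2 <- sum((ys - xs * b)^2 / v) / (n - 1)
  list(delta = delta, sg2 = sg2, se2 = sg2 * delta, mu = b,
       boundary = FALSE)
}

floor_eigen <- function(K, floor = 1e-8) {
  ek <- eigen(K, symmetric = TRUE)
  if (any(!is.finite(ek$values))) stop("kinship matrix is not PSD")
  ek$values <- pmax(ek$values, floor)
  ek
}

#' Mixed-model association scan (EMMAX-style P3D)
#'
#' Fits `y = mu + x b + u + e` with `cov(u) = sg2 K` and `cov(e) = se2 I`.
#' The variance components are estimated once on the null model (no SNP) by
#' REML via the eigendecomposition of `K`; every SNP is then tested by
#' generalized least squares in the rotated space with those components
#' fixed (the "population parameters previously determined" approximation),
#' using a two-sided Wald t-test on `n - 2` degrees of freedom.  Missing
#' genotypes are mean-imputed per SNP.
#'
#' @param phenotype Named numeric vector (names = line ids) or plain vector
#'   aligned to the genotype rows.
#' @param genotypes A `geno_matrix`.
#' @param K Kinship matrix from [ibs_kinship()] (computed from `genotypes`
#'   when omitted).
#' @param eig Optional precomputed eigendecomposition of `K` (from
#'   `eigen(K, symmetric = TRUE)`), reused across scans of the same panel.
#' @return data.frame (`snp`, `chrom`, `pos`, `maf`, `beta`, `se`, `p`)
#'   with attributes `sg2`, `se2`, `delta` and `model = "lmm"`.
#' @export
lmm_scan <- function(phenotype, genotypes, K = NULL, eig = NULL) {
  y <- align_phenotype(phenotype, genotypes)
  if (stats::sd(y) == 0) stop("constant phenotype")
  n <- length(y)
  if (is.null(eig)) {
    if (is.null(K)) K <- ibs_kinship(genotypes)
    eig <- floor_eigen(K)
  } else {
    eig$values <- pmax(eig$values, 1e-8)
  }
  fit <- reml_null(y, eig)
  delta <- if (is.finite(fit$delta)) fit$delta else 1e8
  U <- eig$vectors
  w <- 1 / (eig$values + delta)
  w <- w / mean(w)     # scale-free: the Wald t is invariant to scaling w
  ys <- crossprod(U, y)[, 1]
  xs0 <- crossprod(U, rep(1, n))[, 1]
  Gs <- crossprod(U, impute_mean(genotypes$G))
  s11 <- sum(w * xs0^2)
  s12 <- colSums(w * xs0 * Gs)
  s22 <- colSums(w * Gs^2)
  t1 <- sum(w * xs0 * ys)
  t2 <- colSums(w * Gs * ys)
  det <- s11 * s22 - s12^2
  det[det < 1e-10 * s11 * pmax(s22, 1e-300)] <- NA
  beta <- (s11 * t2 - s12 * t1) / det
  beta0 <- (s22 * t1 - s12 * t2) / det
  rss <- sum(w * ys^2) - (beta0 * t1 + beta * t2)
  rss[rss < 0] <- 0
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * s11 / det)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  res <- data.frame(snp = genotypes$map$snp, chrom = genotypes$map$chrom,
                    pos = genotypes$map$pos, maf = genotypes$map$maf,
                    beta = beta, se = se, p = p, stringsAsFactors = FALSE)
  structure(res, sg2 = fit$sg2, se2 = fit$se2, delta = fit$delta,
            model = "lmm")
}

#' Linear-model association scan (no structure correction)
#'
#' Per-SNP ordinary least squares with a two-sided t-test on the slope.
#' Missing genotypes are mean-imputed per SNP.
#'
#' @inheritParams lmm_scan
#' @return data.frame as in [lmm_scan()] with attribute `model = "lm"`.
#' @export
lm_scan <- function(phenotype, genotypes) {
  y <- align_phenotype(phenotype, genotypes)
  if (stats::sd(y) == 0) stop("constant phenotype")
  n <- length(y)
  G <- impute_mean(genotypes$G)
  yc <- y - mean(y)
  gc <- sweep(G, 2, colMeans(G))
  sxy <- colSums(gc * yc)
  sxx <- colSums(gc^2)
  syy <- sum(yc^2)
  sxx[sxx < 1e-12] <- NA
  beta <- sxy / sxx
  r2 <- pmin(sxy^2 / (sxx * syy), 1)
  sigma2 <- syy * (1 - r2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[!is.finite(p)] <- .Machine$double.xmin      # perfect fit underflow cap
  p <- pmax(p, .Machine$double.xmin)
  res <- data.frame(snp = genotypes$map$snp, chrom = genotypes$map$chrom,
                    pos = genotypes$map$pos, maf = genotypes$map$maf,
                    beta = beta, se = se, p = p, stringsAsFactors = FALSE)
  structure(res, model = "lm")
}

align_phenotype <- function(phenotype, genotypes) {
  y <- phenotype
  if (!is.null(names(y))) {
    if (!all(rownames(genotypes$G) %in% names(y)))
      stop("phenotype missing lines present in genotypes")
    y <- y[rownames(genotypes$G)]
  } else if (length(y) != nrow(genotypes$G)) {
    stop("phenotype length does not match number of lines")
  }
  if (anyNA(y)) stop("missing phenotype values; subset lines first")
  as.numeric(y)
}

impute_mean <- function(G) {
  if (!anyNA(G)) return(G)
  mu <- colMeans(G, na.rm = TRUE)
  ix <- which(is.na(G), arr.ind = TRUE)
  G[ix] <- mu[ix[, 2]]
  G
}

#' Box-Cox transform of a positive phenotype
#'
#' The power parameter lambda is chosen on the grid `[-2, 2]` (step 0.01)
#' maximizing the Box-Cox profile log-likelihood (via [MASS::boxcox()]);
#' the data are transformed as `(y^lambda - 1) / lambda` (`log y` at
#' lambda = 0).  Used to normalize expression phenotypes before scanning.
#'
#' @param values Strictly positive numeric vector.
#' @return list(`values` = transformed vector, `lambda`).
#' @export
boxcox_transform <- function(values) {
  v <- values[!is.na(values)]
  if (any(v <= 0)) stop("Box-Cox requires strictly positive values")
  grid <- seq(-2, 2, by = 0.01)
  bc <- MASS::boxcox(v ~ 1, data = data.frame(v = v), lambda = grid,
                     plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  tr <- if (abs(lambda) < 1e-12) log(values)
        else (values^lambda - 1) / lambda
  list(values = tr, lambda = lambda)
}

#' Variance explained by a single SNP
#'
#' Squared Pearson correlation between genotype and phenotype.
#'
#' @param snp Genotype vector (0/1).
#' @param phenotype Numeric vector aligned to `snp`.
#' @return r-squared in `[0, 1]`.
#' @export
variance_explained <- function(snp, phenotype) {
  if (length(snp) != length(phenotype)) stop("unaligned vectors")
  if (stats::sd(snp) == 0 || stats::sd(phenotype) == 0)
    stop("constant input")
  stats::cor(snp, phenotype)^2
}
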
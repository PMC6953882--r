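#' Standardized linkage disequilibrium D' between two SNPs
#'
#' With haploid-coded inbred lines the haplotypes are observed directly:
#' `D = p_AB - p_A * p_B`, and `D' = D / Dmax` where `Dmax` is
#' `min(p_A (1 - p_B), (1 - p_A) p_B)` for positive D and
#' `min(p_A p_B, (1 - p_A)(1 - p_B))` for negative D (signed; `D' = 0`
#' when `D = 0`).
#'
#' @param snpA,snpB 0/1 genotype vectors over the same lines.
#' @return list of class `ld_pair`: haplotype counts `n_AB`, `n_Ab`,
#'   `n_aB`, `n_ab`, frequencies `p_A`, `p_B`, `p_AB`, and `D`, `Dmax`,
#'   `dprime`, `r2`.
#' @export
d_prime <- function(snpA, snpB) {
  if (length(snpA) != length(snpB)) stop("unaligned SNP vectors")
  ok <- !is.na(snpA) & !is.na(snpB)
  a <- snpA[ok]; b <- snpB[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("monomorphic SNP")
  n <- length(a)
  n_AB <- sum(a == 1 & b == 1); n_Ab <- sum(a == 1 & b == 0)
  n_aB <- sum(a == 0 & b == 1); n_ab <- sum(a == 0 & b == 0)
  p_A <- mean(a); p_B <- mean(b); p_AB <- n_AB / n
  D <- p_AB - p_A * p_B
  Dmax <- if (D > 0) min(p_A * (1 - p_B), (1 - p_A) * p_B)
          else min(p_A * p_B, (1 - p_A) * (1 - p_B))
  dprime <- if (D == 0) 0 else D / Dmax
  structure(list(n_AB = n_AB, n_Ab = n_Ab, n_aB = n_aB, n_ab = n_ab,
                 p_A = p_A, p_B = p_B, p_AB = p_AB,
                 D = D, Dmax = Dmax, dprime = dprime,
                 r2 = stats::cor(a, b)^2),
            class = "ld_pair")
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("ld_pair: D = %.4f, D' = %.3f, r2 = %.3f (pA = %.3f, pB = %.3f)\n",
              x$D, x$dprime, x$r2, x$p_A, x$p_B))
  invisible(x)
}

#' Matched-MAF empirical null for inter-locus D'
#'
#' How unusual is the observed D' between a target SNP and a partner SNP?
#' The null distribution is built from all SNPs whose MAF matches the
#' partner's within `tol`, located on chromosomes other than either focal
#' SNP's (so genuine linkage cannot enter the null).  The one-sided
#' empirical p-value counts null pairs with D' as or more extreme in the
#' hypothesis direction (add-one rule).  The default direction `"less"`
#' tests for repulsion -- depletion of the double-carrier haplotype, the
#' natural alternative when selection is suspected to act against the
#' allele combination -- and is fixed a priori, which keeps the empirical
#' p uniform under independence; `"observed"` follows the sign of the
#' observed D' instead (and is then bounded near 0.5 under the null).
#' One-sided Fisher's exact tests for depletion of the double-carrier
#' haplotype are returned for the observed and all null pairs.
#'
#' @param genotypes A `geno_matrix`.
#' @param target_snp,partner_snp SNP identifiers or column indices.
#' @param tol MAF matching tolerance (absolute, default 0.005 = +/-0.5
#'   percentage points).
#' @param min_matched Minimum size of the matched set (default 50).
#' @param direction `"less"` (repulsion, default), `"greater"` (coupling)
#'   or `"observed"` (toward the observed sign).
#' @return list(`observed` = `ld_pair`, `p_empirical`, `null_dprime`,
#'   `fisher_p_observed`, `fisher_p_null`, `n_matched`, `direction`).
#' @export
matched_maf_null <- function(genotypes, target_snp, partner_snp,
                             tol = 0.005, min_matched = 50L,
                             direction = c("less", "greater", "observed")) {
  direction <- match.arg(direction)
  it <- snp_column(genotypes, target_snp)
  ip <- snp_column(genotypes, partner_snp)
  map <- genotypes$map
  g_t <- genotypes$G[, it]
  obs <- d_prime(g_t, genotypes$G[, ip])
  excl_chr <- unique(c(map$chrom[it], map$chrom[ip]))
  matched <- which(abs(map$maf - map$maf[ip]) <= tol &
                     !(map$chrom %in% excl_chr))
  matched <- setdiff(matched, c(it, ip))
  if (length(matched) < min_matched)
    stop("only ", length(matched), " MAF-matched SNPs (need ", min_matched,
         "); widen tol")
  null_dp <- numeric(length(matched))
  fisher_null <- numeric(length(matched))
  for (i in seq_along(matched)) {
    lp <- d_prime(g_t, genotypes$G[, matched[i]])
    null_dp[i] <- lp$dprime
    fisher_null[i] <- fisher_exact_1sided(haplotype_table(lp))
  }
  dir_eff <- if (direction == "observed") {
    if (obs$dprime < 0) "less" else "greater"
  } else direction
  extreme <- if (dir_eff == "less") null_dp <= obs$dprime
             else null_dp >= obs$dprime
  p_emp <- (1 + sum(extreme)) / (length(matched) + 1)
  list(observed = obs, p_empirical = p_emp, null_dprime = null_dp,
       fisher_p_observed = fisher_exact_1sided(haplotype_table(obs)),
       fisher_p_null = fisher_null, n_matched = length(matched),
       direction = direction)
}

haplotype_table <- function(lp) {
  matrix(c(lp$n_AB, lp$n_Ab, lp$n_aB, lp$n_ab), 2, byrow = TRUE)
}

#' One-sided Fisher's exact test for double-carrier depletion
#'
#' Hypergeometric tail probability of observing the double-carrier
#' haplotype count (cell `[1, 1]`) this low or lower given the margins --
#' small p means the two alternative alleles co-occur less often than
#' independence predicts.
#'
#' @param counts 2x2 matrix of haplotype counts
#'   `rbind(c(n_AB, n_Ab), c(n_aB, n_ab))`.
#' @return p-value.
#' @export
fisher_exact_1sided <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("counts must be integers")
  stats::fisher.test(counts, alternative = "less")$p.value
}

#' Multi-locus genotype-combination frequencies
#'
#' Counts every observed multi-locus genotype combination and compares it
#' with the expectation under independence of the loci (random mating in an
#' inbred panel): `expected = n * prod(per-locus allele frequencies)`.
#'
#' @param genotypes A `geno_matrix`.
#' @param snps Vector of SNP identifiers (>= 1).
#' @return data.frame with one row per combination: the per-SNP alleles,
#'   `observed`, `expected`, `ratio`.
#' @export
genotype_combination_frequencies <- function(genotypes, snps) {
  cols <- vapply(snps, function(s) snp_column(genotypes, s), 0L)
  G <- genotypes$G[, cols, drop = FALSE]
  n <- nrow(G)
  f <- colMeans(G)
  combos <- expand.grid(rep(list(0:1), length(cols)))
  names(combos) <- paste0("allele_", seq_along(cols))
  key <- apply(G, 1, paste, collapse = "/")
  combo_key <- apply(combos, 1, paste, collapse = "/")
  observed <- as.integer(table(factor(key, levels = combo_key)))
  expected <- n * apply(combos, 1, function(a)
    prod(ifelse(a == 1, f, 1 - f)))
  out <- cbind(combos, observed = observed, expected = expected,
               ratio = observed / expected)
  attr(out, "snps") <- snps
  out
}

#' Per-line average methylation over GWAS-targeted TEs
#'
#' The targeted-TE set is defined by the strength of each TE's association
#' with the focal SNP (`-log10 p >= threshold`); the phenotype is each
#' line's unweighted mean level over that set.
#'
#' @param pheno Matrix lines x TEs of methylation levels.
#' @param scores Named vector of per-TE `-log10 p` association scores with
#'   the focal SNP.
#' @param threshold_log10p Score threshold (default 6, the genome-wide
#'   value used on large panels; desk-scale runs need a lower,
#'   panel-calibrated value).
#' @return Named per-line means with attribute `te_set`.
#' @export
targeted_te_average <- function(pheno, scores, threshold_log10p = 6) {
  te <- names(scores)[!is.na(scores) & scores >= threshold_log10p]
  te <- intersect(te, colnames(pheno))
  if (!length(te))
    stop("no TE reaches -log10 p >= ", threshold_log10p,
         "; lower the threshold for desk-scale panels")
  out <- rowMeans(pheno[, te, drop = FALSE], na.rm = TRUE)
  attr(out, "te_set") <- te
  out
}

#' Longitudinal cline regression
#'
#' OLS of a per-line value on longitude within the configured window.
#' With `covariate_snp`, the value is first regressed on the allele and the
#' residuals are regressed on longitude -- if the cline is entirely
#' mediated by the allele, the residual regression is null.
#'
#' @param values Named per-line numeric vector.
#' @param metadata data.frame with `line_id` and `longitude`.
#' @param covariate_snp Optional genotype vector (named) or SNP id.
#' @param genotypes Optional `geno_matrix` to resolve `covariate_snp`.
#' @param lon_range Longitude window (default `c(-25, 100)`).
#' @return list of class `cline_result`: `slope`, `r2`, `p`, `n`,
#'   `covariate`.
#' @export
longitude_cline <- function(values, metadata, covariate_snp = NULL,
                            genotypes = NULL, lon_range = c(-25, 100)) {
  lon <- metadata$longitude[match(names(values), metadata$line_id)]
  keep <- !is.na(lon) & lon >= lon_range[1] & lon <= lon_range[2] &
    !is.na(values)
  if (sum(keep) < 10) stop("fewer than 10 lines in the longitude window")
  y <- values[keep]; lon <- lon[keep]
  covariate <- "none"
  if (!is.null(covariate_snp)) {
    g <- if (is.numeric(covariate_snp) && length(covariate_snp) == length(values))
      covariate_snp[keep]
    else {
      if (is.null(genotypes)) stop("supply genotypes to resolve covariate_snp")
      genotypes$G[names(values)[keep], snp_column(genotypes, covariate_snp)]
    }
    y <- stats::residuals(stats::lm(y ~ g))
    covariate <- "allele"
  }
  fit <- stats::lm(y ~ lon)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 r2 = sm$r.squared,
                 p = sm$coefficients[2, 4],
                 n = length(y), covariate = covariate),
            class = "cline_result")
}

#' @export
print.cline_result <- function(x, ...) {
  cat(sprintf("cline: slope = %.3g, r2 = %.4f, p = %.3g (n = %d, covariate = %s)\n",
              x$slope, x$r2, x$p, x$n, x$covariate))
  invisible(x)
}

#' BLUP structure correction of a phenotype
#'
#' Fits `value = mu + u + e` with `cov(u) = sg2 K` by REML, predicts the
#' random effect by its BLUP, and returns the centered values minus the
#' BLUP -- the phenotype with the kinship-structured component removed.
#' When the REML estimate of `sg2` is zero (including the flat-likelihood
#' case `K = I`), the centered values are returned unchanged.
#'
#' @param values Named per-line numeric vector.
#' @param K Kinship matrix aligned to (or named like) `values`.
#' @return Corrected values (centered scale).
#' @export
blup_correct <- function(values, K) {
  if (!is.null(rownames(K)) && !is.null(names(values)))
    K <- K[names(values), names(values)]
  eig <- floor_eigen(K)
  fit <- reml_null(values, eig)
  centered <- values - mean(values)
  if (fit$boundary || fit$sg2 <= 0) return(centered)
  shrink <- eig$values / (eig$values + fit$delta)
  u <- eig$vectors %*% (shrink * crossprod(eig$vectors, centered))
  out <- centered - as.numeric(u)
  names(out) <- names(values)
  out
}
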
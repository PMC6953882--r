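#' Per-TE differential methylation by allele
#'
#' For every TE, the mean methylation level of lines carrying the
#' alternative allele minus the mean of reference-allele lines
#' (alt - ref: a negative DML means the alternative allele decreases
#' methylation).
#'
#' @param pheno Matrix lines x TEs of methylation levels.
#' @param snp Genotype vector (0/1) aligned to the rows of `pheno`, or a
#'   SNP identifier resolved against `genotypes`.
#' @param genotypes Optional `geno_matrix` used to resolve `snp` ids.
#' @param snp_name Label used in error messages.
#' @return data.frame (`te_id`, `dml`, `n_ref`, `n_alt`) of class
#'   `effect_profile`.
#' @export
dml_by_allele <- function(pheno, snp, genotypes = NULL, snp_name = "snp") {
  if (!is.numeric(snp) || length(snp) != nrow(pheno)) {
    if (is.null(genotypes)) stop("snp must be a genotype vector or supply genotypes")
    snp_name <- as.character(snp)
    snp <- genotypes$G[rownames(pheno), snp_column(genotypes, snp)]
  }
  alt <- snp == 1
  if (sum(alt) == 0 || sum(!alt) == 0)
    stop("allele group empty for SNP ", snp_name)
  dml <- colMeans(pheno[alt, , drop = FALSE], na.rm = TRUE) -
    colMeans(pheno[!alt, , drop = FALSE], na.rm = TRUE)
  structure(data.frame(te_id = colnames(pheno), dml = as.numeric(dml),
                       n_ref = sum(!alt), n_alt = sum(alt),
                       stringsAsFactors = FALSE),
            class = c("effect_profile", "data.frame"), source = snp_name)
}

#' Spearman correlation of an allelic profile with a mutant panel
#'
#' Rank correlation of the per-TE allelic DML with each mutant's DML over
#' the TEs shared between profile and panel, sorted by decreasing
#' correlation.
#'
#' @param allele_profile An `effect_profile` from [dml_by_allele()].
#' @param mutant_panel A `mutant_panel` matrix (mutants x TEs).
#' @return Named numeric vector of Spearman r per mutant (decreasing).
#' @export
allele_mutant_correlation <- function(allele_profile, mutant_panel) {
  shared <- intersect(allele_profile$te_id, colnames(mutant_panel))
  if (length(shared) < 10) stop("fewer than 10 shared TEs")
  x <- allele_profile$dml[match(shared, allele_profile$te_id)]
  r <- apply(mutant_panel[, shared, drop = FALSE], 1, function(m)
    stats::cor(x, m, method = "spearman"))
  sort(r, decreasing = TRUE)
}

#' Permutation null for an allele-mutant correlation
#'
#' Tests whether the observed Spearman correlation between a focal SNP's
#' allelic DML profile and a mutant profile is stronger than expected for
#' an arbitrary SNP: `n_perm` SNPs are drawn uniformly at random from the
#' (MAF-filtered) genome, each one's DML profile is correlated with the
#' mutant profile, and the two-sided empirical p-value is
#' `(1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1)` -- never exactly zero by
#' the add-one rule.  Columns identical to the focal SNP are excluded from
#' the draw (on a small genome the focal SNP would otherwise enter its own
#' null).
#'
#' @param pheno Matrix lines x TEs of methylation levels.
#' @param genotypes A `geno_matrix`, already MAF-filtered.
#' @param mutant_profile Named numeric vector of per-TE mutant DML (names
#'   matching `colnames(pheno)`), or a row of a `mutant_panel`.
#' @param focal_snp SNP identifier or genotype vector for the observed
#'   correlation.
#' @param n_perm Number of permutation SNPs (default 1500; below 100 the
#'   resolution `1/(n_perm+1)` is warned about).
#' @param seed Integer seed.
#' @return list(`p`, `r_obs`, `r_perm`, `n_perm`).
#' @export
permutation_null <- function(pheno, genotypes, mutant_profile, focal_snp,
                             n_perm = 1500, seed = 1L) {
  if (n_perm < 100)
    warning("n_perm < 100: empirical p resolution is only 1/(n_perm+1)")
  set.seed(seed)
  te <- intersect(colnames(pheno), names(mutant_profile))
  if (length(te) < 10) stop("fewer than 10 shared TEs")
  P <- pheno[, te, drop = FALSE]
  mp_rank <- rank(mutant_profile[te])

  obs <- dml_by_allele(P, focal_snp, genotypes)
  r_obs <- stats::cor(rank(obs$dml), mp_rank)

  G <- genotypes$G[rownames(P), , drop = FALSE]
  gf <- if (is.numeric(focal_snp) && length(focal_snp) == nrow(P)) focal_snp
        else G[, snp_column(genotypes, focal_snp)]
  eligible <- which(colSums(G != gf) > 0)
  cols <- eligible[sample.int(length(eligible), n_perm,
                              replace = n_perm > length(eligible))]
  Gp <- G[, cols, drop = FALSE]
  n_alt <- colSums(Gp)
  ok <- n_alt > 0 & n_alt < nrow(Gp)
  Gp <- Gp[, ok, drop = FALSE]; n_alt <- n_alt[ok]
  ## vectorized group means: (TE x lines) %*% (lines x n_perm)
  M1 <- crossprod(P, Gp)
  M0 <- crossprod(P, 1 - Gp)
  D <- sweep(M1, 2, n_alt, "/") - sweep(M0, 2, nrow(Gp) - n_alt, "/")
  Dr <- apply(D, 2, rank)
  r_perm <- as.numeric(stats::cor(Dr, mp_rank))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (length(r_perm) + 1)
  list(p = p, r_obs = r_obs, r_perm = r_perm, n_perm = length(r_perm))
}

#' Joint two-locus genotype metaplot and central-bin tests
#'
#' Splits lines into the (up to four) two-locus genotype combinations,
#' computes each combination's 60-bin metaplot over a TE set, and tests
#' methylation differences at the TE center (mean of the two central body
#' bins) by Welch's t-test: marginally for each locus and for the
#' double-carrier vs double-reference contrast.  Empty combinations are
#' dropped with a warning (rare combinations may be absent).
#'
#' @param counts A `methyl_counts` object with positional bins.
#' @param snpA,snpB SNP identifiers or genotype vectors.
#' @param te_set TE ids (e.g. one target class).
#' @param genotypes Optional `geno_matrix` to resolve SNP ids.
#' @return list(`profiles` = combinations x 60 matrix (rownames like
#'   "A0/B1"), `center` = per-line central-bin levels, `tests` =
#'   data.frame of Welch tests).
#' @export
joint_genotype_profile <- function(counts, snpA, snpB, te_set,
                                   genotypes = NULL) {
  if (!length(te_set)) stop("te_class empty")
  gA <- resolve_snp_vec(snpA, counts, genotypes)
  gB <- resolve_snp_vec(snpB, counts, genotypes)
  combo <- factor(sprintf("A%d/B%d", gA, gB),
                  levels = c("A0/B0", "A1/B0", "A0/B1", "A1/B1"))
  present <- table(combo) > 0
  if (any(!present))
    warning("dropping empty genotype combination(s): ",
            paste(names(present)[!present], collapse = ", "))
  combo <- droplevels(combo)
  profiles <- metaplot_profile(counts, te_set, combo)

  te_ix <- match(te_set, colnames(counts$mc))
  mc_c <- counts$bins$mc[, te_ix, 30:31, drop = FALSE]
  tot_c <- counts$bins$total[, te_ix, 30:31, drop = FALSE]
  center <- rowSums(mc_c, dims = 1) / rowSums(tot_c, dims = 1)

  welch <- function(sel1, sel0, contrast) {
    x <- center[sel1]; y <- center[sel0]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    tt <- stats::t.test(x, y)
    data.frame(contrast = contrast, t = unname(tt$statistic),
               p = tt$p.value, mean_1 = mean(x), mean_0 = mean(y),
               n_1 = length(x), n_0 = length(y), stringsAsFactors = FALSE)
  }
  tests <- rbind(
    welch(gA == 1, gA == 0, "A_alt_vs_ref"),
    welch(gB == 1, gB == 0, "B_alt_vs_ref"),
    welch(gA == 1 & gB == 1, gA == 0 & gB == 0, "double_vs_none"))
  list(profiles = profiles, center = center, tests = tests)
}

resolve_snp_vec <- function(snp, counts, genotypes) {
  if (is.numeric(snp) && length(snp) == nrow(counts$mc)) return(snp)
  if (is.null(genotypes)) stop("supply genotypes to resolve SNP ids")
  genotypes$G[rownames(counts$mc), snp_column(genotypes, snp)]
}

#' Expression difference between allele groups
#'
#' Two-sided Welch's unequal-variance t-test of an expression phenotype
#' between alternative- and reference-allele lines.
#'
#' @param expr Named numeric expression vector.
#' @param snp Genotype vector or SNP identifier.
#' @param genotypes Optional `geno_matrix` to resolve `snp`.
#' @return list(`t`, `p`, `mean_ref`, `mean_alt`, `n_ref`, `n_alt`).
#' @export
expression_by_allele <- function(expr, snp, genotypes = NULL) {
  if (!is.numeric(snp) || length(snp) != length(expr)) {
    if (is.null(genotypes)) stop("supply genotypes to resolve SNP ids")
    snp <- genotypes$G[names(expr), snp_column(genotypes, snp)]
  }
  x <- expr[snp == 1]; y <- expr[snp == 0]
  if (length(x) < 2 || length(y) < 2) stop("allele group with < 2 lines")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, p = 1, mean_ref = mean(y), mean_alt = mean(x),
                  n_ref = length(y), n_alt = length(x)))
    stop("zero variance in both groups")
  }
  tt <- stats::t.test(x, y)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_ref = mean(y), mean_alt = mean(x),
       n_ref = length(y), n_alt = length(x))
}
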
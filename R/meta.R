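#' Combine per-phenotype p-values by Fisher's method
#'
#' For each SNP, `X2 = -2 * sum(log(p_i))` over the k component scans;
#' under the global null `X2` follows a chi-square distribution with `2k`
#' degrees of freedom, and the combined p-value is its upper tail at the
#' observed statistic.  Component p-values of exactly zero are clamped to
#' `1e-300` with a warning (a zero would make the statistic infinite).
#'
#' Note that the component scans of a family-level meta-analysis are
#' correlated phenotypes of the same panel, so the chi-square reference is
#' anti-conservative to an unknown degree; the enrichment FDR downstream
#' calibrates the threshold empirically rather than relying on this null.
#'
#' @param p_values Numeric vector (one SNP, k scans) or matrix
#'   (SNPs x scans); entries in (0, 1].
#' @return For a vector, a one-row data.frame; for a matrix, one row per
#'   SNP: columns `X2`, `df`, `p`.
#' @export
fisher_combine <- function(p_values) {
  pm <- if (is.matrix(p_values)) p_values else matrix(p_values, nrow = 1)
  if (any(pm > 1, na.rm = TRUE)) stop("p-value > 1")
  if (any(pm < 0, na.rm = TRUE)) stop("negative p-value")
  if (any(pm == 0, na.rm = TRUE)) {
    warning("p-value(s) of 0 clamped to 1e-300")
    pm[pm == 0] <- 1e-300
  }
  k <- ncol(pm)
  X2 <- -2 * rowSums(log(pm))
  p <- stats::pchisq(X2, df = 2 * k, lower.tail = FALSE)
  data.frame(X2 = X2, df = 2 * k, p = pmax(p, .Machine$double.xmin))
}

#' Gene-level significance from a SNP-level meta-analysis
#'
#' Each gene is assigned the most significant combined p-value among SNPs
#' with MAF above `maf_min` inside its span extended by `window` on both
#' sides (closed interval: a SNP exactly `window` bp away counts).  Genes
#' with no SNP in the window get `NA` and are excluded from the FDR
#' computation.
#'
#' @param meta data.frame with `chrom`, `pos`, `maf`, `p` per SNP
#'   (e.g. [fisher_combine()] output bound to the SNP map).
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @param window Window in bp (default 15000).
#' @param maf_min MAF floor for eligible SNPs (default 0.05, strict).
#' @return data.frame (`gene_id`, `p`, `score` = -log10 p, `n_snps`).
#' @export
gene_level_significance <- function(meta, genes, window = 15000,
                                    maf_min = 0.05) {
  meta <- meta[meta$maf > maf_min, , drop = FALSE]
  best_p <- rep(NA_real_, nrow(genes))
  n_snps <- integer(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    si <- which(meta$chrom == ch)
    if (!length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(meta$pos[si], width = 1L),
      IRanges::IRanges(pmax(1L, genes$start[gi] - window),
                       genes$end[gi] + window))
    if (!length(hits)) next
    byg <- split(meta$p[si][S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits))
    idx <- gi[as.integer(names(byg))]
    best_p[idx] <- vapply(byg, min, 0)
    n_snps[idx] <- lengths(byg)
  }
  data.frame(gene_id = genes$gene_id, p = best_p,
             score = -log10(best_p), n_snps = n_snps,
             stringsAsFactors = FALSE)
}

#' Enrichment-calibrated FDR threshold
#'
#' The genome-wide significance threshold is calibrated against an a priori
#' list of candidate genes: for each candidate threshold t (descending over
#' the observed gene scores), the FDR estimate is the add-one-smoothed
#' fraction of background genes scoring >= t divided by the leave-one-out
#' fraction of a priori genes scoring >= t, capped at 1.  The reported
#' threshold is the smallest t with `FDR(t) <= target_fdr`.  Thresholds
#' supported by fewer than `min_a_priori` a priori genes are skipped.
#' These are stability guards on a ratio of tail counts: candidate
#' thresholds are the observed scores themselves, so the a priori gene
#' sitting at a threshold always counts itself as "enriched" there
#' (leave-one-out removes that self-selection), and without the guards the
#' one or two best-scoring a priori genes claim a spurious threshold in a
#' sizable fraction of exchangeable-null panels.
#'
#' @param gene_sig Output of [gene_level_significance()] (genes with `NA`
#'   scores are dropped).
#' @param a_priori_ids Character vector of a priori gene ids.
#' @param target_fdr Target FDR (default 0.2).
#' @param min_a_priori Minimum a priori exceedance count (default 3).
#' @return list(`threshold` = -log10 p threshold or `NA` if none qualifies,
#'   `curve` = data.frame(threshold, fdr, n_background, n_a_priori),
#'   `target_fdr`).
#' @export
enrichment_fdr <- function(gene_sig, a_priori_ids, target_fdr = 0.2,
                           min_a_priori = 3L) {
  gs <- gene_sig[!is.na(gene_sig$score), , drop = FALSE]
  is_ap <- gs$gene_id %in% a_priori_ids
  if (!any(is_ap)) stop("no a priori gene with a non-missing score")
  ap <- gs$score[is_ap]
  bg <- gs$score[!is_ap]
  ts <- sort(unique(gs$score), decreasing = TRUE)
  n_ap <- vapply(ts, function(t) sum(ap >= t), 0L)
  n_bg <- vapply(ts, function(t) sum(bg >= t), 0L)
  fdr <- pmin(((n_bg + 1) / (length(bg) + 1)) /
                (pmax(n_ap - 1, 0) / length(ap)), 1)
  fdr[n_ap == 0] <- NA_real_
  curve <- data.frame(threshold = ts, fdr = fdr,
                      n_background = n_bg, n_a_priori = n_ap)
  ok <- !is.na(fdr) & fdr <= target_fdr & n_ap >= min_a_priori
  threshold <- if (any(ok)) min(ts[ok]) else NA_real_
  list(threshold = threshold, curve = curve, target_fdr = target_fdr)
}

#' Linkage disequilibrium r-squared of two SNPs
#'
#' Squared correlation of the haploid allele indicators.
#'
#' @param snpA,snpB 0/1 genotype vectors over the same lines.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(snpA, snpB) {
  if (length(snpA) != length(snpB)) stop("unaligned SNP vectors")
  if (stats::sd(snpA) == 0 || stats::sd(snpB) == 0)
    stop("monomorphic SNP")
  stats::cor(snpA, snpB)^2
}

#' Greedy LD pruning of candidate peaks
#'
#' Candidates are sorted by decreasing X2 (ties broken by genomic order);
#' a SNP is retained iff its r-squared with every already-retained SNP is
#' at most `r2_cut`, otherwise it is recorded as absorbed by the retained
#' SNP it is linked to -- i.e. of two linked SNPs the one with the lower X2
#' is excluded.
#'
#' @param candidates data.frame with `snp`, `chrom`, `pos`, `X2` (and
#'   optionally `p`).
#' @param genotypes A `geno_matrix` containing the candidate SNPs.
#' @param r2_cut LD threshold (default 0.2).
#' @return The retained rows, with a list-column `absorbed` of pruned SNP
#'   ids per peak.
#' @export
ld_prune <- function(candidates, genotypes, r2_cut = 0.2) {
  if (nrow(candidates) == 0) return(cbind(candidates, absorbed = list()))
  o <- order(-candidates$X2, candidates$chrom, candidates$pos)
  cand <- candidates[o, , drop = FALSE]
  cols <- vapply(cand$snp, function(s) snp_column(genotypes, s), 0L)
  G <- genotypes$G[, cols, drop = FALSE]
  keep <- integer(0)
  absorbed <- list()
  for (i in seq_len(nrow(cand))) {
    if (length(keep)) {
      r2 <- vapply(keep, function(j) ld_r2(G[, i], G[, j]), 0)
      if (any(r2 > r2_cut)) {
        j <- keep[which.max(r2)]
        absorbed[[j]] <- c(absorbed[[j]], cand$snp[i])
        next
      }
    }
    keep <- c(keep, i)
    absorbed[[i]] <- character(0)
  }
  out <- cand[keep, , drop = FALSE]
  out$absorbed <- absorbed[keep]
  rownames(out) <- NULL
  out
}
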
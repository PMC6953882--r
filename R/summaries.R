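#' Weighted methylation level
#'
#' The weighted methylation level of a region is the ratio of summed
#' methylated-read counts to summed covered-read counts -- not the mean of
#' per-site ratios, which would overweight low-coverage sites.
#'
#' @param mc_counts Non-negative integer vector of methylated-read counts.
#' @param total_counts Covered-read counts, elementwise `>= mc_counts`.
#' @return A level in `[0, 1]`, or `NA` when total coverage is zero.
#' @export
weighted_methylation <- function(mc_counts, total_counts) {
  if (length(mc_counts) != length(total_counts))
    stop("mc_counts and total_counts must have equal length")
  if (any(mc_counts < 0, na.rm = TRUE) || any(total_counts < 0, na.rm = TRUE))
    stop("negative counts")
  if (any(mc_counts > total_counts, na.rm = TRUE))
    stop("mc_count exceeds total_count")
  tot <- sum(total_counts, na.rm = TRUE)
  if (tot == 0) return(NA_real_)
  sum(mc_counts, na.rm = TRUE) / tot
}

#' Common-TE filter
#'
#' Returns the TEs with nonzero read coverage in every listed line,
#' preserving annotation (column) order.  Downstream analyses are restricted
#' to these "common" TEs so that every phenotype is defined for every line.
#'
#' @param counts A `methyl_counts` object (or list with a `total` matrix,
#'   lines x TEs).
#' @param lines Line ids to require coverage in; defaults to all lines.
#' @return Character vector of TE ids.
#' @export
common_te_filter <- function(counts, lines = rownames(counts$total)) {
  if (length(lines) == 0) stop("empty line list")
  tot <- counts$total[lines, , drop = FALSE]
  colnames(tot)[colSums(tot > 0) == length(lines)]
}

#' Per-TE weighted methylation phenotype matrix
#'
#' @param counts A `methyl_counts` object.
#' @param te_ids TEs to include (default: common TEs).
#' @return Matrix lines x TEs of levels in `[0, 1]` (`NA` where coverage is
#'   zero), with the TE annotation attached as attribute `annotation`.
#' @export
methylation_phenotype <- function(counts, te_ids = common_te_filter(counts)) {
  mc <- counts$mc[, te_ids, drop = FALSE]
  tot <- counts$total[, te_ids, drop = FALSE]
  lev <- mc / tot
  lev[tot == 0] <- NA_real_
  ann <- counts$annotation
  attr(lev, "annotation") <- ann[match(te_ids, ann$te_id), , drop = FALSE]
  lev
}

#' Family-average methylation phenotypes
#'
#' Per line and TE family, the unweighted mean of member-TE levels.
#' Families with no member among the input TEs are dropped with a warning.
#'
#' @param pheno Matrix lines x TEs (restricted to common TEs).
#' @param family_map Named character vector TE id -> family; must cover
#'   every column of `pheno`.
#' @return Matrix lines x families.
#' @export
family_average <- function(pheno, family_map) {
  missing <- setdiff(colnames(pheno), names(family_map))
  if (length(missing))
    stop("family_map missing TE(s): ", paste(missing, collapse = ", "))
  fam <- family_map[colnames(pheno)]
  empty <- setdiff(unique(family_map), fam)
  if (length(empty))
    warning("dropping families with no common member: ",
            paste(empty, collapse = ", "))
  out <- vapply(split(seq_len(ncol(pheno)), fam),
                function(ix) rowMeans(pheno[, ix, drop = FALSE]),
                numeric(nrow(pheno)))
  rownames(out) <- rownames(pheno)
  out
}

#' Rank transform across lines
#'
#' Ranks 1..n over the non-missing entries, average ranks for ties, missing
#' entries stay missing.  Applied to each phenotype before association
#' scanning, making the scans invariant to monotone transforms of the
#' methylation scale.
#'
#' @param values Numeric vector (one phenotype across lines) or matrix
#'   (ranked per column).
#' @return Ranks of the same shape.
#' @export
rank_transform <- function(values) {
  if (is.matrix(values)) return(apply(values, 2, rank_transform))
  if (sum(!is.na(values)) < 2) stop("need >= 2 non-missing values to rank")
  rank(values, na.last = "keep", ties.method = "average")
}

#' Classify TEs into pathway target classes from knockout DML
#'
#' A TE is called a target of a pathway when the designated knockout of that
#' pathway loses more than `dml_threshold` methylation at it (strict
#' inequality).  Labels: `RdDM` (RdDM-pathway knockout only), `CMT2`
#' (CMT2-like knockout only), `both`, `untargeted`.  Panel DML is
#' mutant-minus-wild-type, so a loss is a negative DML.
#'
#' @param mutant_panel A `mutant_panel` matrix (mutants x TEs).
#' @param dml_threshold Loss threshold (default 0.1).
#' @param classifier Named ids (`rddm`, `cmt2`) of the two classifier
#'   mutants; defaults to the panel's `classifier` attribute.
#' @return list(`labels` = named factor per TE with levels
#'   RdDM/CMT2/both/untargeted, `threshold`, `classifier`).
#' @export
classify_targets <- function(mutant_panel, dml_threshold = 0.1,
                             classifier = attr(mutant_panel, "classifier")) {
  if (is.null(classifier) || !all(c("rddm", "cmt2") %in% names(classifier)))
    stop("classifier mutants not specified")
  if (!all(classifier %in% rownames(mutant_panel)))
    stop("designated classifier mutant absent from panel: ",
         paste(setdiff(classifier, rownames(mutant_panel)), collapse = ", "))
  loss_r <- -mutant_panel[classifier[["rddm"]], ]
  loss_c <- -mutant_panel[classifier[["cmt2"]], ]
  lab <- ifelse(loss_r > dml_threshold & loss_c > dml_threshold, "both",
         ifelse(loss_r > dml_threshold, "RdDM",
         ifelse(loss_c > dml_threshold, "CMT2", "untargeted")))
  labels <- factor(lab, levels = c("RdDM", "CMT2", "both", "untargeted"))
  names(labels) <- colnames(mutant_panel)
  list(labels = labels, threshold = dml_threshold, classifier = classifier)
}

#' Positional metaplot profiles
#'
#' For each group of lines and each of the 60 positional bins (20 upstream,
#' 20 body, 20 downstream), the weighted methylation level across all lines
#' of the group and all TEs of the set.
#'
#' @param counts A `methyl_counts` object with `bins`.
#' @param te_set TE ids to aggregate over.
#' @param groups Factor (or vector) of group assignments, one per line.
#' @return Matrix groups x 60 with attribute `region` marking
#'   upstream/body/downstream.
#' @export
metaplot_profile <- function(counts, te_set, groups) {
  if (is.null(counts$bins)) stop("counts carry no positional bins")
  groups <- as.factor(groups)
  if (any(table(groups) == 0))
    stop("empty genotype group: ",
         paste(levels(groups)[table(groups) == 0], collapse = ", "))
  te_ix <- match(te_set, colnames(counts$mc))
  if (anyNA(te_ix)) stop("unknown TE id in te_set")
  out <- matrix(NA_real_, nlevels(groups), 60,
                dimnames = list(levels(groups), NULL))
  for (g in levels(groups)) {
    lix <- which(groups == g)
    mc <- counts$bins$mc[lix, te_ix, , drop = FALSE]
    tot <- counts$bins$total[lix, te_ix, , drop = FALSE]
    out[g, ] <- colSums(mc, dims = 2) / colSums(tot, dims = 2)
  }
  attr(out, "region") <- rep(c("upstream", "body", "downstream"), each = 20)
  out
}

#' Cluster TE families by their methylation pattern across lines
#'
#' Family levels are rank-transformed within each line (so lines contribute
#' comparable scales), families are compared by Euclidean distance between
#' their across-line rank profiles, and joined by complete-linkage
#' agglomerative clustering; groups are obtained by cutting the tree into
#' `k` clusters.
#'
#' @param family_pheno Matrix lines x families.
#' @param k Number of groups to cut into (default 4).
#' @return list(`hclust` = the tree, `groups` = named integer cluster
#'   labels per family).
#' @export
cluster_families <- function(family_pheno, k = 4) {
  if (ncol(family_pheno) < 4) stop("need >= 4 families")
  if (k > ncol(family_pheno)) stop("k exceeds the number of families")
  ranked <- t(apply(family_pheno, 1, rank, ties.method = "average"))
  hc <- stats::hclust(stats::dist(t(ranked)), method = "complete")
  groups <- stats::cutree(hc, k = k)
  list(hclust = hc, groups = groups)
}
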
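#' Simulate a TE annotation table
#'
#' Places `n_te` TEs on the genome with log-normal lengths, assigns each to
#' a family (families are class-pure), a class-typical superfamily, and a
#' pericentromeric flag (CMT2-class TEs are preferentially pericentromeric,
#' mirroring heterochromatic targeting).  Class counts follow
#' `class_fractions` by largest-remainder allocation, so fractions like
#' 0.5/0.5/0 give exact splits.  Intervals are 0-based half-open and may
#' overlap (the annotation is positional only), but never exceed the
#' chromosome.
#'
#' @param config A [sim_config()]; requires `n_te >= 10`.
#' @param seed Integer seed.
#' @return data.frame with `te_id`, `chrom`, `start`, `end`, `family`,
#'   `superfamily`, `class`, `length`, `pericentromeric`.
#' @export
simulate_te_annotation <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (config$n_te < 10) stop("n_te must be >= 10")
  set.seed(seed + 1L)
  n_te <- config$n_te

  classes <- c("rddm", "cmt2", "untargeted")
  counts <- largest_remainder(config$class_fractions[classes], n_te)
  te_class <- rep(classes, counts)

  ## class-pure families, split proportionally to class fractions
  fam_counts <- largest_remainder(config$class_fractions[classes],
                                  config$n_families)
  fam_counts[fam_counts == 0 & counts > 0] <- 1L
  family <- unlist(lapply(seq_along(classes), function(k) {
    if (counts[k] == 0) return(character(0))
    nf <- max(1L, fam_counts[k])
    ids <- sprintf("%s_fam%02d", classes[k], seq_len(nf))
    sort(sample(ids, counts[k], replace = TRUE))
  }))

  superfams <- list(rddm = c("RC/Helitron", "DNA/MuDR"),
                    cmt2 = c("LTR/Gypsy", "LTR/Copia"),
                    untargeted = c("SINE", "Unassigned"))
  fam_ids <- unique(family)
  fam_class <- sub("_fam.*", "", fam_ids)
  fam_super <- vapply(fam_class, function(cl) sample(superfams[[cl]], 1), "")
  names(fam_super) <- fam_ids

  len <- pmin(round(stats::rlnorm(n_te, log(3000), 0.6)),
              floor(config$chrom_length / 2))
  chrom <- sample.int(config$n_chrom, n_te, replace = TRUE)
  centro <- config$chrom_length / 2
  peri_p <- ifelse(te_class == "cmt2", 0.7, 0.2)
  peri <- stats::runif(n_te) < peri_p
  start <- ifelse(peri,
                  round(stats::runif(n_te, centro - 0.1 * config$chrom_length,
                                     centro + 0.1 * config$chrom_length - len)),
                  round(stats::runif(n_te, 0, config$chrom_length - len)))
  start <- pmax(0, pmin(start, config$chrom_length - len))
  end <- start + len
  if (any(end > config$chrom_length)) stop("TE interval exceeds chromosome length")

  ann <- data.frame(te_id = sprintf("TE%04d", seq_len(n_te)),
                    chrom = chrom, start = start, end = end,
                    family = family, superfamily = fam_super[family],
                    class = te_class, length = len,
                    pericentromeric = peri, stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  ann
}

largest_remainder <- function(frac, total) {
  raw <- frac * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Simulate a gene annotation and a priori candidate list
#'
#' Support table for the meta-analysis stage: evenly spaced genes plus one
#' gene placed over each causal SNP.  The a priori list contains the
#' causal-locus genes and random decoys (default total 79, emulating a
#' curated list of epigenetic-pathway regulators).
#'
#' @param config A [sim_config()].
#' @param n_genes Number of background genes.
#' @param n_a_priori Size of the a priori candidate list.
#' @param gene_width Gene span in bp.
#' @param seed Integer seed.
#' @return list(`genes` = data.frame(gene_id, chrom, start, end),
#'   `a_priori` = character vector of gene ids).
#' @export
simulate_gene_annotation <- function(config, n_genes = 2000L, n_a_priori = 79L,
                                     gene_width = 2000L, seed = config$seed) {
  set.seed(seed + 2L)
  per_chrom <- ceiling(n_genes / config$n_chrom)
  starts <- round(seq(1, config$chrom_length - gene_width, length.out = per_chrom))
  genes <- data.frame(
    chrom = rep(seq_len(config$n_chrom), each = per_chrom),
    start = rep(starts, config$n_chrom))
  genes <- genes[seq_len(min(nrow(genes), n_genes)), ]
  cs <- config$causal_spec
  if (nrow(cs) > 0) {
    causal_genes <- data.frame(chrom = cs$chrom,
                               start = pmax(1, cs$pos - gene_width %/% 2))
    genes <- rbind(genes, causal_genes)
  }
  genes$end <- genes$start + gene_width
  genes <- genes[order(genes$chrom, genes$start), ]
  genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
  rownames(genes) <- NULL

  causal_ids <- character(0)
  if (nrow(cs) > 0)
    causal_ids <- vapply(seq_len(nrow(cs)), function(i) {
      hit <- genes$chrom == cs$chrom[i] & genes$start <= cs$pos[i] &
        genes$end >= cs$pos[i]
      genes$gene_id[which(hit)[1]]
    }, "")
  decoys <- sample(setdiff(genes$gene_id, causal_ids),
                   max(0, n_a_priori - length(unique(causal_ids))))
  list(genes = genes[c("gene_id", "chrom", "start", "end")],
       a_priori = sort(unique(c(causal_ids, decoys))))
}

#' Simulate methylome read counts
#'
#' Builds the latent per-line per-TE mCHH level as
#' class baseline + per-TE offset + planted allelic effects (restricted to
#' each causal SNP's target class, plus any cross-class term) + polygenic
#' background (line effect with covariance proportional to IBS kinship) +
#' iid line-by-class noise + iid cell noise, clipped to `[0, 1]`; observed
#' counts are beta-binomial around the latent level at Poisson depth.
#'
#' With `emit_bins = TRUE` each TE also gets 60 positional bins (20
#' upstream / 20 body / 20 downstream): flank bins carry a reduced baseline,
#' and effects whose target pathway is CMT2-like act on TE bodies only while
#' RdDM-like (and cross-class) effects act over the whole element including
#' the edges.  The per-TE scalar counts are then the body-bin sums, so both
#' paths share the same latent body level.
#'
#' @param genotypes A `geno_matrix` from [simulate_population()].
#' @param annotation TE table from [simulate_te_annotation()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `methyl_counts` object: list with matrices `mc` and `total`
#'   (lines x TEs), optional `bins` (`mc`/`total` arrays lines x TEs x 60),
#'   the TE `annotation`, and the latent `truth` (per-TE expected allelic
#'   effect profile per causal SNP).
#' @export
simulate_methylomes <- function(genotypes, annotation, config,
                                seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed + 3L)
  G <- genotypes$G
  n <- nrow(G); n_te <- nrow(annotation)
  cs <- config$causal_spec
  if (nrow(cs) > 0 && !all(cs$label %in% genotypes$map$label))
    stop("causal_spec loci missing from genotype matrix")

  te_class <- annotation$class
  mu <- config$baseline[te_class] +
    stats::rnorm(n_te, 0, config$sd_te_offset)

  ## planted effect profile per causal SNP (per-TE expected DML)
  truth <- matrix(0, n_te, nrow(cs),
                  dimnames = list(annotation$te_id, cs$label))
  L <- matrix(rep(mu, each = n), n, n_te)
  for (i in seq_len(nrow(cs))) {
    g <- G[, snp_column(genotypes, cs$label[i])]
    prof <- numeric(n_te)
    prof[te_class == cs$target_class[i]] <- cs$effect[i]
    if (!is.na(cs$cross_class[i]) && cs$cross_effect[i] != 0)
      prof[te_class == cs$cross_class[i]] <- prof[te_class == cs$cross_class[i]] +
        cs$cross_effect[i]
    truth[, i] <- prof
    L <- L + outer(g, prof)
  }

  ## line-level effects: polygenic (kinship-structured) + iid per class
  sd_poly <- config$sd_line * sqrt(config$h2_background)
  sd_iid <- config$sd_line * sqrt(1 - config$h2_background)
  if (sd_poly > 0) {
    K <- ibs_kinship(genotypes)
    ek <- eigen(K, symmetric = TRUE)
    a <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * stats::rnorm(n)) * sd_poly
    a <- a - mean(a)   # between-line variation only: the IBS top eigenvector
                       # is near-constant and a panel-wide shift is not a
                       # phenotype difference (it would only drive clipping)
    L <- L + as.vector(a)
  }
  for (cl in unique(te_class)) {
    idx <- te_class == cl
    L[, idx] <- L[, idx] + stats::rnorm(n, 0, sd_iid)
  }
  L <- L + matrix(stats::rnorm(n * n_te, 0, config$sd_te), n, n_te)

  n_clip <- sum(L < 0 | L > 1)
  if (n_clip > 0.05 * length(L))
    warning(sprintf("latent levels clipped in %d cells (%.1f%% > 5%%)",
                    n_clip, 100 * n_clip / length(L)))
  L <- pmin(pmax(L, 0), 1)

  rho <- config$overdispersion
  line_id <- rownames(G); te_id <- annotation$te_id
  if (config$emit_bins) {
    flank_mult <- c(seq(0.15, 0.85, length.out = 20),
                    rep(1, 20),
                    seq(0.85, 0.15, length.out = 20))
    ## effect weights: CMT2-pathway effects body-only, RdDM-like everywhere
    w_body <- c(rep(0.2, 20), rep(1, 20), rep(0.2, 20))
    w_all <- rep(1, 60)
    base_part <- L
    eff_part_body <- matrix(0, n, n_te)
    eff_part_all <- matrix(0, n, n_te)
    for (i in seq_len(nrow(cs))) {
      g <- G[, snp_column(genotypes, cs$label[i])]
      own <- outer(g, ifelse(te_class == cs$target_class[i], cs$effect[i], 0))
      if (cs$target_class[i] == "cmt2") eff_part_body <- eff_part_body + own
      else eff_part_all <- eff_part_all + own
      if (!is.na(cs$cross_class[i]) && cs$cross_effect[i] != 0)
        eff_part_all <- eff_part_all +
          outer(g, ifelse(te_class == cs$cross_class[i], cs$cross_effect[i], 0))
    }
    base_part <- base_part - eff_part_body - eff_part_all
    mc_b <- array(0L, c(n, n_te, 60)); tot_b <- array(0L, c(n, n_te, 60))
    depth_bin <- config$read_depth_mean / 20
    for (b in 1:60) {
      Lb <- base_part * flank_mult[b] + eff_part_body * w_body[b] +
        eff_part_all * w_all[b]
      Lb <- pmin(pmax(Lb, 1e-6), 1 - 1e-6)
      d <- matrix(stats::rpois(n * n_te, depth_bin), n, n_te)
      q <- matrix(stats::rbeta(n * n_te, Lb * (1 - rho) / rho,
                               (1 - Lb) * (1 - rho) / rho), n, n_te)
      mcb <- matrix(stats::rbinom(n * n_te, d, q), n, n_te)
      mc_b[, , b] <- mcb; tot_b[, , b] <- d
    }
    mc <- rowSums(mc_b[, , 21:40, drop = FALSE], dims = 2)
    total <- rowSums(tot_b[, , 21:40, drop = FALSE], dims = 2)
    dimnames(mc) <- dimnames(total) <- list(line_id, te_id)
    bins <- list(mc = mc_b, total = tot_b)
  } else {
    Lc <- pmin(pmax(L, 1e-6), 1 - 1e-6)
    depth <- matrix(stats::rpois(n * n_te, config$read_depth_mean), n, n_te)
    q <- matrix(stats::rbeta(n * n_te, Lc * (1 - rho) / rho,
                             (1 - Lc) * (1 - rho) / rho), n, n_te)
    mc <- matrix(stats::rbinom(n * n_te, depth, q), n, n_te,
                 dimnames = list(line_id, te_id))
    total <- depth; dimnames(total) <- list(line_id, te_id)
    bins <- NULL
  }
  structure(list(mc = mc, total = total, bins = bins,
                 annotation = annotation, truth = truth,
                 n_clipped = n_clip),
            class = "methyl_counts")
}

#' @export
print.methyl_counts <- function(x, ...) {
  cat("methyl_counts:", nrow(x$mc), "lines x", ncol(x$mc), "TEs",
      if (!is.null(x$bins)) "(with 60-bin positional counts)" else "", "\n")
  invisible(x)
}

#' Simulate a loss-of-function mutant methylome panel
#'
#' Emits per-mutant per-TE differential methylation levels (DML,
#' mutant minus wild-type).  The panel contains: two designated classifier
#' knockouts with class-pure losses (`drm1drm2_ko` on RdDM-class TEs,
#' `cmt2_ko` on CMT2-class TEs, loss `classifier_loss`); one matched mutant
#' per causal locus whose profile is `amplification` times the planted
#' allelic effect profile (knockouts are stronger than natural alleles but
#' hit the same targets, so allele and matched-mutant DML correlate
#' positively); and `n_decoys` decoys with random sparse profiles.
#'
#' @param annotation TE table with class labels.
#' @param config A [sim_config()].
#' @param n_decoys Number of decoy mutants (>= 10 by default).
#' @param amplification Scale factor from allelic to knockout effects.
#' @param classifier_loss Methylation loss of the classifier knockouts on
#'   their target class.
#' @param noise_sd Per-TE noise of every mutant profile (0 gives exact
#'   construction).
#' @param seed Integer seed.
#' @return A `mutant_panel`: DML matrix mutants x TEs with attributes
#'   `classifier` (named ids of the two classifier mutants) and `matched`
#'   (causal label -> mutant id).
#' @export
simulate_mutant_panel <- function(annotation, config, n_decoys = 12L,
                                  amplification = 4, classifier_loss = 0.2,
                                  noise_sd = 0.02, seed = config$seed) {
  if (!"class" %in% names(annotation)) stop("annotation lacks class labels")
  set.seed(seed + 4L)
  n_te <- nrow(annotation)
  cs <- config$causal_spec
  profs <- list(
    drm1drm2_ko = -classifier_loss * (annotation$class == "rddm"),
    cmt2_ko     = -classifier_loss * (annotation$class == "cmt2"))
  matched <- character(0)
  for (i in seq_len(nrow(cs))) {
    prof <- numeric(n_te)
    prof[annotation$class == cs$target_class[i]] <- cs$effect[i]
    if (!is.na(cs$cross_class[i]))
      prof[annotation$class == cs$cross_class[i]] <-
        prof[annotation$class == cs$cross_class[i]] + cs$cross_effect[i]
    id <- paste0("mut_", cs$label[i])
    profs[[id]] <- amplification * prof
    matched[cs$label[i]] <- id
  }
  for (d in seq_len(n_decoys)) {
    prof <- numeric(n_te)
    hit <- stats::runif(n_te) < 0.1
    prof[hit] <- stats::runif(sum(hit), -0.3, 0.1)
    profs[[sprintf("decoy%02d", d)]] <- prof
  }
  panel <- do.call(rbind, profs)
  if (noise_sd > 0)
    panel <- panel + matrix(stats::rnorm(length(panel), 0, noise_sd),
                            nrow(panel))
  panel <- pmin(pmax(panel, -1), 1)
  colnames(panel) <- annotation$te_id
  structure(panel,
            classifier = c(rddm = "drm1drm2_ko", cmt2 = "cmt2_ko"),
            matched = matched,
            class = c("mutant_panel", "matrix", "array"))
}

#' Simulate an expression phenotype with a cis effect
#'
#' Strictly positive, log-normally distributed expression with an additive
#' shift (in units of the baseline standard deviation) for carriers of a
#' designated cis allele.
#'
#' @param genotypes A `geno_matrix`.
#' @param config A [sim_config()].
#' @param cis_snp SNP (label, id or "chr:pos") carrying the cis effect.
#' @param shift Effect size in baseline-SD units for alternative carriers.
#' @param meanlog,sdlog Log-normal baseline parameters.
#' @param seed Integer seed.
#' @return Named numeric vector of expression values (names = line ids)
#'   with attribute `cis_snp`.
#' @export
simulate_expression <- function(genotypes, config, cis_snp = "cmt2_plus",
                                shift = 1, meanlog = log(50), sdlog = 0.4,
                                seed = config$seed) {
  set.seed(seed + 5L)
  g <- genotypes$G[, snp_column(genotypes, cis_snp)]
  base <- stats::rlnorm(length(g), meanlog, sdlog)
  expr <- base + shift * stats::sd(base) * g
  expr <- pmax(expr, .Machine$double.eps)
  names(expr) <- rownames(genotypes$G)
  attr(expr, "cis_snp") <- cis_snp
  expr
}
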
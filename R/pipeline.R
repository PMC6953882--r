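## End-to-end orchestration: simulate -> summarize -> gwas -> meta ->
## effects -> geo.  Each stage reads its inputs from the output directory
## and writes TSVs there, so any stage can be re-run in isolation; a JSON
## manifest records per-file checksums and the derived per-stage seeds.

PIPELINE_STAGES <- c("simulate", "summarize", "gwas", "meta", "effects", "geo")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order.  Every stochastic
#' stage receives a sub-seed derived from the master seed and the stage
#' index (bitwise XOR), so identical (config, seed) runs are bitwise
#' reproducible and individual stages can be re-run without disturbing the
#' others.
#'
#' @param config A [sim_config()], or a path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (default `config$seed`).
#' @param stages Subset of
#'   `c("simulate", "summarize", "gwas", "meta", "effects", "geo")`.
#' @param params Named list of analysis tunables: `maf` (filter threshold,
#'   0.05), `fdr` (0.2), `window` (15000), `r2` (LD prune cut, 0.2),
#'   `n_perm` (1500), `targeted_log10p` (desk-scale default 1.5),
#'   `maf_tol` (0.005).
#' @return The run manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL,
                         stages = PIPELINE_STAGES, params = list()) {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  seed <- as.integer(seed)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- utils::modifyList(list(maf = 0.05, fdr = 0.2, window = 15000,
                              r2 = 0.2, n_perm = 1500,
                              targeted_log10p = 1.5, maf_tol = 0.005),
                         params)

  deps <- list(
    simulate = character(0),
    summarize = c("genotypes.tsv", "methyl_counts.tsv"),
    gwas = c("genotypes.tsv", "family_phenotypes.tsv"),
    meta = c("family_scans.tsv", "genes.tsv"),
    effects = c("te_phenotypes.tsv", "mutant_panel.tsv"),
    geo = c("te_phenotypes.tsv", "line_metadata.tsv"))

  manifest <- list(config_hash = digest_obj(config), seed = seed,
                   stages = list())
  for (st in PIPELINE_STAGES) {
    if (!(st %in% stages)) next
    idx <- match(st, PIPELINE_STAGES)
    sub_seed <- bitwXor(seed, idx)
    missing <- deps[[st]][!file.exists(file.path(out_dir, deps[[st]]))]
    if (length(missing))
      stop("stage '", st, "' is missing upstream output(s): ",
           paste(missing, collapse = ", "),
           "; run the producing stage first")
    files <- switch(st,
      simulate = stage_simulate(config, out_dir, sub_seed),
      summarize = stage_summarize(config, out_dir),
      gwas = stage_gwas(config, out_dir, p),
      meta = stage_meta(config, out_dir, p),
      effects = stage_effects(config, out_dir, p, sub_seed),
      geo = stage_geo(config, out_dir, p))
    manifest$stages[[st]] <- list(
      seed = sub_seed, outputs = as.list(unname(
        tools::md5sum(file.path(out_dir, files)))))
    names(manifest$stages[[st]]$outputs) <- files
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

digest_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf)
  unname(tools::md5sum(tf))
}

## ---- stages -------------------------------------------------------------

stage_simulate <- function(config, out_dir, sub_seed) {
  pop <- simulate_population(config, seed = sub_seed)
  ann <- simulate_te_annotation(config, seed = sub_seed)
  counts <- simulate_methylomes(pop$geno, ann, config, seed = sub_seed)
  panel <- simulate_mutant_panel(ann, config, seed = sub_seed)
  genes <- simulate_gene_annotation(config, seed = sub_seed)
  expr <- simulate_expression(pop$geno, config, seed = sub_seed)

  write_genotypes_vcf(pop$geno, file.path(out_dir, "genotypes.vcf"))
  write_genotypes_tsv(pop$geno, file.path(out_dir, "genotypes.tsv"))
  write_schema_tsv(pop$geno$map, file.path(out_dir, "snp_map.tsv"))
  write_schema_tsv(pop$meta, file.path(out_dir, "line_metadata.tsv"))
  write_te_annotation(ann, file.path(out_dir, "te_annotation.bed"))
  write_methyl_counts(counts, file.path(out_dir, "methyl_counts.tsv"))
  pdf <- data.frame(mutant_id = rownames(panel), as.data.frame(unclass(panel)),
                    check.names = FALSE)
  write_schema_tsv(pdf, file.path(out_dir, "mutant_panel.tsv"))
  write_schema_tsv(genes$genes, file.path(out_dir, "genes.tsv"))
  writeLines(genes$a_priori, file.path(out_dir, "a_priori_genes.txt"))
  write_schema_tsv(data.frame(line_id = names(expr), expression = expr),
                   file.path(out_dir, "expression.tsv"))

  c("genotypes.vcf", "genotypes.tsv", "snp_map.tsv", "line_metadata.tsv",
    "te_annotation.bed", "methyl_counts.tsv", "mutant_panel.tsv",
    "genes.tsv", "a_priori_genes.txt", "expression.tsv")
}

## Stages exchange data exclusively through the files in out_dir, so a
## stage re-run in a fresh session reproduces byte-identical outputs.
pipeline_geno <- function(out_dir) {
  g <- read_genotypes(file.path(out_dir, "genotypes.tsv"))
  mp <- read_schema_tsv(file.path(out_dir, "snp_map.tsv"))
  lab <- mp$label[match(g$map$snp, mp$snp)]
  lab[!is.na(lab) & lab == ""] <- NA   # NA round-trips as "" in TSV
  g$map$label <- lab
  g
}

pipeline_counts <- function(out_dir) {
  ann <- read_te_annotation(file.path(out_dir, "te_annotation.bed"))
  read_methyl_counts(file.path(out_dir, "methyl_counts.tsv"), ann)
}

pipeline_panel <- function(out_dir) {
  df <- read_schema_tsv(file.path(out_dir, "mutant_panel.tsv"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$mutant_id
  lbl <- grep("^mut_", rownames(m), value = TRUE)
  structure(m, classifier = c(rddm = "drm1drm2_ko", cmt2 = "cmt2_ko"),
            matched = stats::setNames(lbl, sub("^mut_", "", lbl)),
            class = c("mutant_panel", "matrix", "array"))
}

stage_summarize <- function(config, out_dir) {
  counts <- pipeline_counts(out_dir)
  panel <- pipeline_panel(out_dir)
  common <- common_te_filter(counts)
  pheno <- methylation_phenotype(counts, common)
  ann <- counts$annotation
  fam_map <- stats::setNames(ann$family, ann$te_id)
  fam <- family_average(pheno, fam_map[common])
  cls <- classify_targets(panel)
  clust <- cluster_families(fam, k = min(4, ncol(fam)))

  write_schema_tsv(data.frame(line_id = rownames(pheno),
                              as.data.frame(pheno), check.names = FALSE),
                   file.path(out_dir, "te_phenotypes.tsv"))
  write_schema_tsv(data.frame(line_id = rownames(fam), as.data.frame(fam),
                              check.names = FALSE),
                   file.path(out_dir, "family_phenotypes.tsv"))
  write_schema_tsv(data.frame(te_id = names(cls$labels),
                              class = as.character(cls$labels)),
                   file.path(out_dir, "te_classification.tsv"))
  write_dendrogram_newick(clust$hclust,
                          file.path(out_dir, "family_dendrogram.nwk"))
  c("te_phenotypes.tsv", "family_phenotypes.tsv", "te_classification.tsv",
    "family_dendrogram.nwk")
}

pipeline_pheno <- function(out_dir, file) {
  df <- read_schema_tsv(file.path(out_dir, file))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line_id
  m
}

stage_gwas <- function(config, out_dir, p) {
  geno <- maf_filter(pipeline_geno(out_dir), p$maf)
  fam <- pipeline_pheno(out_dir, "family_phenotypes.tsv")
  K <- ibs_kinship(geno)
  eig <- floor_eigen(K)
  scans <- lapply(colnames(fam), function(f)
    lmm_scan(rank_transform(fam[, f]), geno, eig = eig))
  names(scans) <- colnames(fam)
  long <- do.call(rbind, lapply(names(scans), function(f)
    cbind(family = f, scans[[f]][c("snp", "chrom", "pos", "maf", "beta", "p")])))
  write_schema_tsv(long, file.path(out_dir, "family_scans.tsv"))
  "family_scans.tsv"
}

stage_meta <- function(config, out_dir, p) {
  long <- read_schema_tsv(file.path(out_dir, "family_scans.tsv"))
  fams <- unique(long$family)
  map <- long[long$family == fams[1], c("snp", "chrom", "pos", "maf")]
  pmat <- vapply(fams, function(f)
    long$p[long$family == f][match(map$snp, long$snp[long$family == f])],
    numeric(nrow(map)))
  meta <- cbind(map, fisher_combine(pmat))
  genes <- read_schema_tsv(file.path(out_dir, "genes.tsv"))
  a_priori <- readLines(file.path(out_dir, "a_priori_genes.txt"))
  gsig <- gene_level_significance(meta, genes, window = p$window)
  fdr <- enrichment_fdr(gsig, a_priori, target_fdr = p$fdr)
  thr <- fdr$threshold
  peaks <- data.frame()
  if (!is.na(thr)) {
    cand <- meta[-log10(meta$p) >= thr, , drop = FALSE]
    geno <- maf_filter(pipeline_geno(out_dir), p$maf)
    peaks <- ld_prune(cand[c("snp", "chrom", "pos", "X2", "p")], geno,
                      r2_cut = p$r2)
    peaks$absorbed <- vapply(peaks$absorbed, paste, "", collapse = ",")
  }
  write_schema_tsv(meta, file.path(out_dir, "meta_scan.tsv"))
  write_schema_tsv(gsig, file.path(out_dir, "gene_significance.tsv"))
  write_schema_tsv(fdr$curve, file.path(out_dir, "fdr_curve.tsv"))
  write_schema_tsv(if (nrow(peaks)) peaks else
    data.frame(snp = character(), chrom = integer(), pos = integer(),
               X2 = numeric(), p = numeric(), absorbed = character()),
    file.path(out_dir, "peaks.tsv"))
  c("meta_scan.tsv", "gene_significance.tsv", "fdr_curve.tsv", "peaks.tsv")
}

stage_effects <- function(config, out_dir, p, sub_seed) {
  pheno <- pipeline_pheno(out_dir, "te_phenotypes.tsv")
  geno <- maf_filter(pipeline_geno(out_dir), p$maf)
  panel <- pipeline_panel(out_dir)
  labels <- stats::na.omit(geno$map$label)
  out <- list()
  for (lb in labels) {
    prof <- dml_by_allele(pheno, lb, geno)
    corr <- allele_mutant_correlation(prof, panel)
    matched <- attr(panel, "matched")[[lb]]
    pn <- permutation_null(pheno, geno, panel[matched, ], lb,
                           n_perm = p$n_perm, seed = sub_seed)
    out[[lb]] <- data.frame(allele = lb, matched_mutant = matched,
                            best_mutant = names(corr)[1],
                            r_best = corr[1],
                            r_matched = corr[[matched]],
                            p_perm = pn$p)
    write_schema_tsv(prof, file.path(out_dir, sprintf("dml_%s.tsv", lb)))
  }
  eff <- do.call(rbind, out)
  write_schema_tsv(eff, file.path(out_dir, "allele_effects.tsv"))
  c("allele_effects.tsv", sprintf("dml_%s.tsv", labels))
}

stage_geo <- function(config, out_dir, p) {
  pheno <- pipeline_pheno(out_dir, "te_phenotypes.tsv")
  geno <- maf_filter(pipeline_geno(out_dir), p$maf)
  meta_lines <- read_schema_tsv(file.path(out_dir, "line_metadata.tsv"))
  K <- ibs_kinship(geno)
  labels <- stats::na.omit(geno$map$label)
  rows <- list()
  for (lb in labels) {
    scores <- focal_te_scores(pheno, geno, lb, K)
    tavg <- tryCatch(targeted_te_average(pheno, scores, p$targeted_log10p),
                     error = function(e) NULL)
    if (is.null(tavg)) next
    raw <- longitude_cline(tavg, meta_lines, lon_range = config$lon_range)
    res <- longitude_cline(tavg, meta_lines, covariate_snp = lb,
                           genotypes = geno, lon_range = config$lon_range)
    blup <- blup_correct(tavg, K)
    bl <- longitude_cline(blup, meta_lines, lon_range = config$lon_range)
    rows[[lb]] <- data.frame(
      allele = lb, n_targeted = length(attr(tavg, "te_set")),
      slope = raw$slope, r2 = raw$r2, p = raw$p,
      r2_resid = res$r2, p_resid = res$p,
      r2_blup = bl$r2, p_blup = bl$p)
  }
  clines <- do.call(rbind, rows)
  write_schema_tsv(clines, file.path(out_dir, "clines.tsv"))

  files <- "clines.tsv"
  if (length(labels) >= 2) {
    ld_rows <- list()
    for (i in seq_along(labels)) for (j in seq_along(labels)) {
      if (i >= j) next
      gi <- geno$G[, snp_column(geno, labels[i])]
      gj <- geno$G[, snp_column(geno, labels[j])]
      lp <- d_prime(gi, gj)
      mn <- tryCatch(matched_maf_null(geno, labels[i], labels[j],
                                      tol = p$maf_tol),
                     error = function(e) NULL)
      ld_rows[[paste(i, j)]] <- data.frame(
        snpA = labels[i], snpB = labels[j], D = lp$D, dprime = lp$dprime,
        r2 = lp$r2,
        p_empirical = if (is.null(mn)) NA else mn$p_empirical,
        fisher_p = fisher_exact_1sided(haplotype_table(lp)),
        n_matched = if (is.null(mn)) NA else mn$n_matched)
    }
    write_schema_tsv(do.call(rbind, ld_rows),
                     file.path(out_dir, "ld_pairs.tsv"))
    combos <- genotype_combination_frequencies(geno, labels)
    write_schema_tsv(combos, file.path(out_dir, "genotype_combinations.tsv"))
    files <- c(files, "ld_pairs.tsv", "genotype_combinations.tsv")
  }
  files
}

#' Per-TE association scores with a focal SNP
#'
#' Mixed-model (P3D) single-SNP association of every TE's rank-transformed
#' methylation level with one SNP; used to define the targeted-TE set.
#'
#' @param pheno Matrix lines x TEs.
#' @param genotypes A `geno_matrix`.
#' @param snp SNP identifier.
#' @param K Kinship matrix.
#' @return Named vector of `-log10 p` per TE.
#' @export
focal_te_scores <- function(pheno, genotypes, snp, K = ibs_kinship(genotypes)) {
  i <- snp_column(genotypes, snp)
  g1 <- new_geno_matrix(genotypes$G[, i, drop = FALSE],
                        genotypes$map[i, , drop = FALSE])
  eig <- floor_eigen(K)
  scores <- vapply(colnames(pheno), function(te) {
    y <- rank_transform(pheno[, te])
    -log10(lmm_scan(y, g1, eig = eig)$p)
  }, 0)
  names(scores) <- colnames(pheno)
  scores
}

#' Validate pipeline input files
#'
#' Checks format dialects (VCF header, TSV schema lines, BED sanity) and
#' line-ID consistency across files.
#'
#' @param paths Named list/vector with any of `genotypes` (VCF or TSV),
#'   `methyl_counts`, `metadata`, `te_annotation`.
#' @return data.frame of issues (`file`, `issue`); zero rows when clean.
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(f, msg) issues[[length(issues) + 1]] <<-
    data.frame(file = f, issue = msg, stringsAsFactors = FALSE)
  for (f in unlist(paths)) if (!file.exists(f)) note(f, "file does not exist")

  line_sets <- list()
  if (!is.null(paths$genotypes) && file.exists(paths$genotypes)) {
    f <- paths$genotypes
    if (grepl("\\.vcf(\\.gz)?$", f)) {
      hdr <- readLines(f, n = 1)
      if (!grepl("^##fileformat=VCF", hdr)) note(f, "missing VCF header")
    }
    g <- tryCatch(read_genotypes(f), error = function(e) NULL)
    if (is.null(g)) note(f, "unparseable genotypes")
    else line_sets$genotypes <- rownames(g$G)
  }
  if (!is.null(paths$methyl_counts) && file.exists(paths$methyl_counts)) {
    f <- paths$methyl_counts
    cnt <- tryCatch(read_methyl_counts(f), error = function(e) e)
    if (inherits(cnt, "error")) note(f, conditionMessage(cnt))
    else line_sets$methyl_counts <- rownames(cnt$mc)
  }
  if (!is.null(paths$metadata) && file.exists(paths$metadata)) {
    md <- read_schema_tsv(paths$metadata)
    if (!all(c("line_id", "longitude") %in% names(md)))
      note(paths$metadata, "metadata lacks line_id/longitude")
    else line_sets$metadata <- md$line_id
  }
  if (!is.null(paths$te_annotation) && file.exists(paths$te_annotation)) {
    ann <- tryCatch(read_te_annotation(paths$te_annotation),
                    error = function(e) e)
    if (inherits(ann, "error")) note(paths$te_annotation, conditionMessage(ann))
  }
  if (length(line_sets) > 1) {
    ref <- line_sets[[1]]
    for (nm in names(line_sets)[-1]) {
      diff <- c(setdiff(ref, line_sets[[nm]]), setdiff(line_sets[[nm]], ref))
      if (length(diff))
        note(nm, paste("line-ID mismatch vs", names(line_sets)[1], ":",
                       paste(utils::head(diff, 10), collapse = ",")))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(file = character(), issue = character())
}
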
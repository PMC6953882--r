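test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(class_fractions = c(rddm = 0.5, cmt2 = 0.4,
                                              untargeted = 0.2)),
               "sum to 1")
  expect_error(sim_config(overdispersion = 0), "overdispersion")
  expect_error(sim_config(h2_background = 1.5), "h2_background")
  expect_error(sim_config(n_lines = 3), "n_lines")
  cs <- default_causal_spec(); cs$maf[1] <- 0.7
  expect_error(sim_config(causal_spec = cs), "MAF")
})

test_that("config survives a YAML round trip", {
  cfg <- tiny_config(seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$n_lines, cfg$n_lines)
  expect_equal(cfg2$causal_spec$effect, cfg$causal_spec$effect)
  expect_equal(cfg2$class_fractions, cfg$class_fractions)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- tiny_config(seed = 7)
  p1 <- simulate_population(cfg); p2 <- simulate_population(cfg)
  expect_identical(p1$geno$G, p2$geno$G)
  expect_identical(p1$meta, p2$meta)
  a1 <- simulate_te_annotation(cfg); a2 <- simulate_te_annotation(cfg)
  expect_identical(a1, a2)
  m1 <- simulate_methylomes(p1$geno, a1, cfg)
  m2 <- simulate_methylomes(p2$geno, a2, cfg)
  expect_identical(m1$mc, m2$mc)
  k1 <- simulate_mutant_panel(a1, cfg); k2 <- simulate_mutant_panel(a2, cfg)
  expect_identical(unclass(k1), unclass(k2))
  # a different seed changes the data
  expect_false(identical(p1$geno$G,
                         simulate_population(cfg, seed = 8)$geno$G))
})

test_that("realized causal MAFs respect the +/-20% relative band", {
  cfg <- tiny_config(n_lines = 200, seed = 3)
  pop <- simulate_population(cfg)
  map <- pop$geno$map
  for (i in seq_len(nrow(cfg$causal_spec))) {
    lab <- cfg$causal_spec$label[i]
    target <- cfg$causal_spec$maf[i]
    realized <- map$maf[match(lab, map$label)]
    expect_lt(abs(realized - target), 0.2 * target + 1e-9)
  }
  # unreachable MAF errors with the locus named
  cs <- default_causal_spec()[1, ]
  cs$maf <- 0.004
  expect_error(simulate_population(tiny_config(n_lines = 30, causal_spec = cs)),
               "trans_rddm")
})

test_that("a zero cline slope plants no longitude association", {
  cs <- default_causal_spec()[3, ]   # flat allele
  cs$maf <- 0.3
  n_sig <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_lines = 120, n_snps = 30, n_te = 10, n_families = 2,
                      causal_spec = cs, seed = 100 + s)
    pop <- simulate_population(cfg)
    g <- pop$geno$G[, chhscan:::snp_column(pop$geno, "cmt2_plus")]
    p <- stats::cor.test(pop$meta$longitude, g)$p.value
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 1L)
})

test_that("with no divergence, background allele counts are binomial", {
  cfg <- sim_config(n_lines = 400, n_snps = 300, n_te = 10, n_families = 2,
                    n_subpop = 1, fst = 0,
                    causal_spec = default_causal_spec()[0, ], seed = 5)
  pop <- simulate_population(cfg)
  p0 <- pop$geno$map$anc_freq
  counts <- colSums(pop$geno$G)
  z <- (counts - 400 * p0) / sqrt(400 * p0 * (1 - p0))
  gof <- stats::pchisq(sum(z^2), df = length(z), lower.tail = FALSE)
  expect_gt(gof, 0.01)
})

test_that("TE annotation allocates classes exactly and reproducibly", {
  cfg <- sim_config(n_lines = 10, n_snps = 20, n_te = 100, n_families = 10,
                    class_fractions = c(rddm = 0.5, cmt2 = 0.5, untargeted = 0),
                    seed = 2)
  ann <- simulate_te_annotation(cfg)
  expect_equal(as.vector(table(ann$class)[c("cmt2", "rddm")]), c(50L, 50L))
  expect_identical(ann, simulate_te_annotation(cfg))
  expect_true(all(ann$end <= cfg$chrom_length))
  expect_true(all(ann$start >= 0))
  # overlap between TEs is permitted: two long TEs on a short chromosome
  cfg2 <- sim_config(n_lines = 10, n_snps = 20, n_te = 10, n_families = 2,
                     chrom_length = 50000, n_chrom = 1,
                     causal_spec = default_causal_spec()[0, ], seed = 4)
  expect_s3_class(simulate_te_annotation(cfg2), "data.frame")
  # families are class-pure
  ann_cl <- unique(ann[c("family", "class")])
  expect_equal(nrow(ann_cl), length(unique(ann$family)))
})

test_that("methylome generator recovers its own planted parameters", {
  # planted effect -0.05 on CMT2-class TEs at n = 500, depth 40
  cs <- default_causal_spec()[2, ]  # cmt2_minus only
  # low line-level noise so the class means isolate the planted effect
  cfg <- sim_config(n_lines = 500, n_snps = 60, n_te = 200, n_families = 10,
                    causal_spec = cs, sd_line = 0.02, h2_background = 0,
                    seed = 11)
  pop <- simulate_population(cfg)
  ann <- simulate_te_annotation(cfg)
  cnt <- simulate_methylomes(pop$geno, ann, cfg)
  lev <- cnt$mc / cnt$total
  g <- pop$geno$G[, chhscan:::snp_column(pop$geno, "cmt2_minus")]
  cls <- ann$class
  diff_by_class <- vapply(c("cmt2", "rddm", "untargeted"), function(cl) {
    m <- lev[, cls == cl, drop = FALSE]
    mean(colMeans(m[g == 1, ]) - colMeans(m[g == 0, ]))
  }, 0)
  expect_lt(abs(diff_by_class[["cmt2"]] - (-0.05)), 0.015)
  # class separation: no planted effect on other classes
  expect_lt(abs(diff_by_class[["rddm"]]), 0.01)
  expect_lt(abs(diff_by_class[["untargeted"]]), 0.01)
})

test_that("null methylomes have only line-level variance at high depth", {
  cfg <- sim_config(n_lines = 300, n_snps = 40, n_te = 60, n_families = 4,
                    causal_spec = default_causal_spec()[0, ],
                    read_depth_mean = 4000, overdispersion = 1e-4,
                    sd_te = 0, h2_background = 0, sd_line = 0.05,
                    sd_te_offset = 0, seed = 13)
  pop <- simulate_population(cfg)
  ann <- simulate_te_annotation(cfg)
  cnt <- simulate_methylomes(pop$geno, ann, cfg)
  lev <- cnt$mc / cnt$total
  v <- apply(lev, 2, stats::var)
  # per-TE variance across lines approaches sd_line^2 = 0.0025
  expect_lt(abs(median(v) - 0.0025), 0.0008)
})

test_that("binned counts carry the class-specific positional signatures", {
  cfg <- sim_config(n_lines = 150, n_snps = 200, n_te = 120, n_families = 8,
                    emit_bins = TRUE, seed = 17)
  pop <- simulate_population(cfg)
  ann <- simulate_te_annotation(cfg)
  cnt <- suppressWarnings(simulate_methylomes(pop$geno, ann, cfg))
  expect_equal(dim(cnt$bins$mc), c(150, 120, 60))
  expect_true(all(cnt$bins$mc <= cnt$bins$total))
  # scalar counts equal body-bin sums
  expect_equal(rowSums(cnt$bins$mc[, , 21:40], dims = 2), cnt$mc,
               ignore_attr = TRUE)
  # CMT2-class negative allele depletes the body but spares flanks
  g <- pop$geno$G[, chhscan:::snp_column(pop$geno, "cmt2_minus")]
  cmt2_te <- ann$te_id[ann$class == "cmt2"]
  prof <- metaplot_profile(cnt, cmt2_te, factor(g, levels = 0:1,
                                                labels = c("ref", "alt")))
  body_drop <- mean(prof["ref", 21:40]) - mean(prof["alt", 21:40])
  flank_drop <- mean(prof["ref", c(1:20, 41:60)]) -
    mean(prof["alt", c(1:20, 41:60)])
  expect_gt(body_drop, 0.03)
  expect_lt(flank_drop, body_drop / 2)
})

test_that("mutant panel matches planted profiles and includes decoys", {
  cfg <- tiny_config(n_te = 1000, n_families = 20, seed = 23)
  ann <- simulate_te_annotation(cfg)
  panel0 <- simulate_mutant_panel(ann, cfg, noise_sd = 0)
  truthprof <- function(lab) {
    cs <- cfg$causal_spec[cfg$causal_spec$label == lab, ]
    prof <- numeric(nrow(ann))
    prof[ann$class == cs$target_class] <- cs$effect
    if (!is.na(cs$cross_class))
      prof[ann$class == cs$cross_class] <- prof[ann$class == cs$cross_class] +
        cs$cross_effect
    prof
  }
  # zero noise: matched mutant profile is a positive multiple of the
  # planted allelic profile (rank correlation 1 over affected TEs)
  pr <- truthprof("trans_rddm")
  keep <- pr != 0
  expect_equal(stats::cor(panel0["mut_trans_rddm", keep], pr[keep],
                          method = "spearman"), 1)
  # decoys are uncorrelated with the planted profile
  decoys <- grep("^decoy", rownames(panel0), value = TRUE)
  expect_gte(length(decoys), 10)
  panel <- simulate_mutant_panel(ann, cfg)
  n_ok <- sum(vapply(decoys, function(d)
    abs(stats::cor(panel[d, ], truthprof("cmt2_minus"),
                   method = "spearman")) < 0.2, TRUE))
  expect_gte(n_ok, length(decoys) - 1)
  expect_identical(unclass(panel), unclass(simulate_mutant_panel(ann, cfg)))
})

test_that("expression generator plants a detectable cis shift", {
  cs <- default_causal_spec()
  power_hits <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_lines = 300, n_snps = 30, n_te = 10, n_families = 2,
                      causal_spec = cs, seed = 300 + s)
    pop <- simulate_population(cfg)
    expr <- simulate_expression(pop$geno, cfg, cis_snp = "cmt2_plus",
                                shift = 1)
    expect_true(all(expr > 0))
    g <- pop$geno$G[, chhscan:::snp_column(pop$geno, "cmt2_plus")]
    tt <- stats::t.test(expr[g == 1], expr[g == 0])
    if (tt$p.value < 0.01 && tt$estimate[1] > tt$estimate[2])
      power_hits <- power_hits + 1L
  }
  expect_gte(power_hits, 9L)
})
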
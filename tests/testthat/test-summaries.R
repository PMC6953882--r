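test_that("weighted methylation is the ratio of summed counts", {
  expect_equal(weighted_methylation(c(2, 3, 0), c(10, 10, 5)), 0.2)
  expect_equal(weighted_methylation(c(0, 0), c(7, 3)), 0)
  expect_true(is.na(weighted_methylation(c(0, 0), c(0, 0))))
  expect_error(weighted_methylation(c(-1, 0), c(5, 5)), "negative")
  expect_error(weighted_methylation(c(6), c(5)), "exceeds")
  expect_error(weighted_methylation(c(1, 2), c(5)), "equal length")
  # ratio of sums, never mean of ratios: these differ on purpose
  mc <- c(1, 9); tot <- c(10, 10)
  expect_equal(weighted_methylation(mc, tot), 0.5)
  expect_false(isTRUE(all.equal(weighted_methylation(c(2, 100), c(10, 1000)),
                                mean(c(2 / 10, 100 / 1000)))))
})

test_that("common-TE filter requires coverage in every line", {
  tot <- rbind(L1 = c(5L, 0L, 3L), L2 = c(2L, 4L, 6L))
  colnames(tot) <- c("TE1", "TE2", "TE3")
  cnt <- list(total = tot, mc = tot * 0L)
  expect_equal(common_te_filter(cnt), c("TE1", "TE3"))
  cnt$total[1, 2] <- 1L
  expect_equal(common_te_filter(cnt), c("TE1", "TE2", "TE3"))
  expect_error(common_te_filter(cnt, lines = character(0)), "empty")
  # the default synthetic config never forces dropout
  cfg <- tiny_config(seed = 31)
  pop <- simulate_population(cfg)
  ann <- simulate_te_annotation(cfg)
  cnt2 <- simulate_methylomes(pop$geno, ann, cfg)
  expect_equal(length(common_te_filter(cnt2)), cfg$n_te)
})

test_that("family averages are unweighted means of member TEs", {
  ph <- cbind(TE1 = c(0.1, 0.4), TE2 = c(0.3, 0.2), TE3 = c(0.9, 0.5))
  rownames(ph) <- c("L1", "L2")
  fm <- c(TE1 = "famA", TE2 = "famA", TE3 = "famB")
  fa <- family_average(ph, fm)
  expect_equal(fa["L1", "famA"], 0.2)
  expect_equal(fa[, "famB"], ph[, "TE3"])          # single-member identity
  perm <- family_average(ph[, c(3, 1, 2)], fm)
  expect_equal(perm[, colnames(fa)], fa)           # member-order symmetry
  expect_error(family_average(ph, fm[-1]), "TE1")
  expect_warning(family_average(ph[, 1:2], fm), "famB")
})

test_that("rank transform uses average ties and keeps missing", {
  expect_equal(rank_transform(c(0.2, 0.5, 0.1)), c(2, 3, 1))
  expect_equal(rank_transform(c(0.2, 0.2, 0.7)), c(1.5, 1.5, 3))
  x <- c(0.3, NA, 0.1, 0.9)
  r <- rank_transform(x)
  expect_true(is.na(r[2]))
  expect_equal(r[-2], c(2, 1, 3))
  # invariant to monotone transforms, idempotent up to ties
  y <- stats::runif(50)
  expect_equal(rank_transform(y), rank_transform(exp(3 * y)))
  expect_equal(rank_transform(rank_transform(y)), rank_transform(y))
  expect_error(rank_transform(c(NA_real_, NA_real_)), "non-missing")
})

test_that("target classification partitions TEs at the 0.1 DML threshold", {
  # panel rows are mutant - wild-type, so a 0.15 loss is DML -0.15
  panel <- rbind(drm1drm2_ko = -c(0.15, 0.12, 0.10, 0.05),
                 cmt2_ko     = -c(0.02, 0.30, 0.10, 0.02))
  colnames(panel) <- paste0("TE", 1:4)
  attr(panel, "classifier") <- c(rddm = "drm1drm2_ko", cmt2 = "cmt2_ko")
  cls <- classify_targets(panel)
  expect_equal(as.character(cls$labels),
               c("RdDM", "both", "untargeted", "untargeted"))
  # exhaustive and exclusive
  expect_false(anyNA(cls$labels))
  expect_error(classify_targets(panel, classifier = c(rddm = "nope",
                                                      cmt2 = "cmt2_ko")),
               "absent")
})

test_that("metaplots are flat without positional signal and reduce to the
           single line in singleton groups", {
  cfg <- sim_config(n_lines = 30, n_snps = 40, n_te = 40, n_families = 4,
                    causal_spec = default_causal_spec()[0, ],
                    read_depth_mean = 4000, overdispersion = 1e-4,
                    sd_line = 0, sd_te = 0, sd_te_offset = 0,
                    h2_background = 0,
                    baseline = c(rddm = 0.3, cmt2 = 0.3, untargeted = 0.3),
                    emit_bins = TRUE, seed = 41)
  pop <- simulate_population(cfg)
  ann <- simulate_te_annotation(cfg)
  cnt <- simulate_methylomes(pop$geno, ann, cfg)
  grp <- rep("all", 30)
  prof <- metaplot_profile(cnt, ann$te_id, grp)
  # body bins sit at the constant latent level
  expect_true(all(abs(prof[1, 21:40] - 0.3) < 0.01))
  # flank bins follow the documented flank-baseline taper, symmetric
  expect_equal(prof[1, 1:20], rev(prof[1, 41:60]), tolerance = 0.05)
  # singleton group equals that line's own binned levels
  grp2 <- c("solo", rep("rest", 29))
  prof2 <- metaplot_profile(cnt, ann$te_id, grp2)
  own <- colSums(cnt$bins$mc[1, , ], dims = 1) /
    colSums(cnt$bins$total[1, , ], dims = 1)
  expect_equal(unname(prof2["solo", ]), unname(own))
  expect_error(metaplot_profile(cnt, ann$te_id,
                                factor(grp, levels = c("all", "ghost"))),
               "ghost")
})

test_that("family clustering recovers planted classes and is stable", {
  set.seed(51)
  # two planted classes with opposite allele responses, small noise
  n <- 60
  g <- rep(0:1, each = n / 2)
  fam_up <- vapply(1:6, function(i) 0.5 + 0.2 * g + rnorm(n, 0, 0.01),
                   numeric(n))
  fam_dn <- vapply(1:6, function(i) 0.5 - 0.2 * g + rnorm(n, 0, 0.01),
                   numeric(n))
  ph <- cbind(fam_up, fam_dn)
  colnames(ph) <- paste0("fam", 1:12)
  cl <- cluster_families(ph, k = 2)
  truth <- rep(1:2, each = 6)
  expect_gt(rand_index(cl$groups, truth), 0.95)
  # duplicated family joins its twin at height zero
  ph2 <- cbind(ph, fam_dup = ph[, 1])
  cl2 <- cluster_families(ph2, k = 2)
  d <- stats::cophenetic(cl2$hclust)
  expect_equal(as.matrix(d)["fam1", "fam_dup"], 0)
  # permuting lines (rows) leaves the tree topology unchanged
  perm <- sample(n)
  cl3 <- cluster_families(ph[perm, ], k = 2)
  expect_equal(stats::cophenetic(cl$hclust), stats::cophenetic(cl3$hclust))
  expect_error(cluster_families(ph, k = 20), "k exceeds")
  expect_error(cluster_families(ph[, 1:3]), ">= 4")
})
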
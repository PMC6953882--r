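test_that("D-prime hits the closed-form LD cases", {
  # perfect coupling at pA = pB = 0.1: D = 0.09, Dmax = 0.09, D' = 1
  h <- toy_haplotypes(10, 0, 0, 90)
  lp <- d_prime(h$a, h$b)
  expect_equal(lp$D, 0.09)
  expect_equal(lp$Dmax, 0.09)
  expect_equal(lp$dprime, 1)
  # complete repulsion at pA = pB = 0.5: D = -0.25, D' = -1
  h2 <- toy_haplotypes(0, 50, 50, 0)
  lp2 <- d_prime(h2$a, h2$b)
  expect_equal(lp2$D, -0.25)
  expect_equal(lp2$dprime, -1)
  # exact independence: D' = 0
  h3 <- toy_haplotypes(25, 25, 25, 25)
  expect_equal(d_prime(h3$a, h3$b)$dprime, 0)
  expect_error(d_prime(h3$a, rep(0, 100)), "monomorphic")
})

test_that("D-prime satisfies its symmetry and bound invariants", {
  set.seed(101)
  for (i in 1:50) {
    a <- stats::rbinom(200, 1, stats::runif(1, 0.1, 0.9))
    b <- stats::rbinom(200, 1, stats::runif(1, 0.1, 0.9))
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    lp <- d_prime(a, b)
    expect_lte(abs(lp$D), lp$Dmax + 1e-12)
    expect_equal(sign(lp$dprime), sign(lp$D))
    expect_gte(lp$dprime, -1 - 1e-12); expect_lte(lp$dprime, 1 + 1e-12)
    # symmetric in argument order
    expect_equal(d_prime(b, a)$dprime, lp$dprime)
    # joint allele-label swap leaves D' unchanged
    expect_equal(d_prime(1 - a, 1 - b)$dprime, lp$dprime)
  }
})

test_that("one-sided exact test matches the hypergeometric tail", {
  # all mass in the off-diagonal: p = choose(5,0) choose(5,5) / choose(10,5)
  expect_equal(fisher_exact_1sided(rbind(c(0, 5), c(5, 0))), 1 / 252,
               tolerance = 1e-12)
  # agreement with the hypergeometric CDF on a generic table
  tab <- rbind(c(3, 7), c(8, 2))
  expect_equal(fisher_exact_1sided(tab),
               stats::phyper(3, 10, 10, 11), tolerance = 1e-12)
  # no depletion signal in a balanced table
  expect_gt(fisher_exact_1sided(rbind(c(25, 25), c(25, 25))), 0.5)
  # double-carrier cell at its maximum: p = 1
  expect_equal(fisher_exact_1sided(rbind(c(5, 0), c(0, 5))), 1)
  expect_error(fisher_exact_1sided(rbind(c(-1, 2), c(3, 4))), "negative")
  expect_error(fisher_exact_1sided(rbind(c(0.5, 2), c(3, 4))), "integers")
})

test_that("matched-MAF null flags planted repulsion and not independence", {
  g <- make_matched_panel(seed = 3, depletion = 0.1)
  res <- matched_maf_null(g, "target", "partner", tol = 0.005)
  expect_gte(res$n_matched, 50)
  expect_lt(res$observed$dprime, -0.5)
  expect_lt(res$p_empirical, 0.01)
  expect_lt(res$fisher_p_observed, 0.01)
  # the partner itself is never in the matched set (chromosome rule)
  expect_equal(res$n_matched, 300)
  # independent partner: unremarkable empirical p
  g0 <- make_matched_panel(seed = 4, depletion = 1)
  res0 <- matched_maf_null(g0, "target", "partner", tol = 0.005)
  expect_gt(res0$p_empirical, 0.01)
  # too few matched SNPs errors with advice
  g_small <- make_matched_panel(n_null = 20, seed = 5)
  expect_error(matched_maf_null(g_small, "target", "partner"), "widen tol")
})

test_that("matched-MAF empirical p is roughly uniform under independence", {
  set.seed(107)
  ps <- vapply(1:40, function(s) {
    g <- make_matched_panel(n = 200, n_null = 120, seed = 200 + s)
    matched_maf_null(g, "target", "partner", tol = 0.005,
                     min_matched = 100)$p_empirical
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("genotype combinations are compared with random mating", {
  set.seed(109)
  n <- 1000
  a <- stats::rbinom(n, 1, 0.3); b <- stats::rbinom(n, 1, 0.4)
  g <- toy_geno(cbind(A = a, B = b), chrom = c(1L, 2L))
  tab <- genotype_combination_frequencies(g, c("A", "B"))
  expect_equal(sum(tab$observed), n)
  dbl <- tab[tab$allele_1 == 1 & tab$allele_2 == 1, ]
  expect_gt(dbl$ratio, 0.7); expect_lt(dbl$ratio, 1.4)
  # planted 10x depletion is detected
  gp <- make_matched_panel(seed = 6, depletion = 0.1, n_null = 60)
  tabp <- genotype_combination_frequencies(gp, c("target", "partner"))
  dblp <- tabp[tabp$allele_1 == 1 & tabp$allele_2 == 1, ]
  expect_lt(dblp$ratio, 0.2)
  # degenerate single-SNP case reduces to allele counts
  tab1 <- genotype_combination_frequencies(g, "A")
  expect_equal(tab1$observed[tab1$allele_1 == 1], sum(a))
})

test_that("targeted-TE averages honor the score threshold", {
  ph <- matrix(stats::runif(50 * 20), 50, 20,
               dimnames = list(sprintf("L%02d", 1:50), sprintf("TE%02d", 1:20)))
  scores <- stats::setNames(c(rep(8, 12), rep(1, 8)), colnames(ph))
  avg <- targeted_te_average(ph, scores, threshold_log10p = 6)
  expect_equal(length(attr(avg, "te_set")), 12)
  # all TEs passing reduces to the genome-wide mean
  avg_all <- targeted_te_average(ph, scores, threshold_log10p = 0)
  expect_equal(as.numeric(avg_all), unname(rowMeans(ph)))
  expect_error(targeted_te_average(ph, scores, threshold_log10p = Inf),
               "lower the threshold")
})

test_that("longitude clines recover exact lines and mediated signals", {
  md <- data.frame(line_id = sprintf("L%03d", 1:200),
                   longitude = stats::runif(200, -25, 100))
  v <- stats::setNames(0.3 + 0.002 * md$longitude, md$line_id)
  cl <- suppressWarnings(longitude_cline(v, md))
  expect_equal(cl$slope, 0.002, tolerance = 1e-10)
  expect_equal(cl$r2, 1, tolerance = 1e-10)
  expect_error(longitude_cline(v[1:5], md[1:5, ]), "fewer than 10")
  # a fully allele-mediated cline loses significance after regression-out
  resid_ok <- 0L; raw_ok <- 0L
  for (s in 1:10) {
    set.seed(1100 + s)
    lon <- stats::runif(300, -25, 100)
    gsnp <- stats::rbinom(300, 1, stats::plogis(-2 + 0.05 * lon))
    y <- stats::setNames(0.3 - 0.05 * gsnp + stats::rnorm(300, 0, 0.02),
                         sprintf("L%03d", 1:300))
    md2 <- data.frame(line_id = names(y), longitude = lon)
    raw <- longitude_cline(y, md2)
    res <- longitude_cline(y, md2, covariate_snp = gsnp)
    if (raw$p < 0.01) raw_ok <- raw_ok + 1L
    if (res$p > 0.05) resid_ok <- resid_ok + 1L
  }
  expect_gte(raw_ok, 9L)
  expect_gte(resid_ok, 9L)
  # value independent of longitude: null p
  v0 <- stats::setNames(stats::rnorm(200), md$line_id)
  expect_gt(longitude_cline(v0, md)$p, 1e-4)
})

test_that("BLUP correction removes kinship-structured signal", {
  # identity kinship: flat likelihood resolves to plain centering
  set.seed(111)
  y <- stats::setNames(stats::rnorm(60), sprintf("L%02d", 1:60))
  KI <- diag(60); dimnames(KI) <- list(names(y), names(y))
  expect_equal(blup_correct(y, KI), y - mean(y), tolerance = 1e-8)
  # two-block kinship with a block-shifted phenotype
  blk <- rep(0:1, each = 30)
  K2 <- 0.15 + 0.7 * outer(blk, blk, "==") + diag(0.15, 60)
  dimnames(K2) <- list(names(y), names(y))
  y2 <- stats::setNames(0.5 * blk + stats::rnorm(60, 0, 0.1), names(y))
  corr <- blup_correct(y2, K2)
  gap_before <- abs(mean(y2[blk == 1]) - mean(y2[blk == 0]))
  gap_after <- abs(mean(corr[blk == 1]) - mean(corr[blk == 0]))
  expect_lt(gap_after, 0.2 * gap_before)
  # idempotent within tolerance
  corr2 <- blup_correct(corr, K2)
  expect_lt(max(abs(corr2 - corr)), 1e-6)
})
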
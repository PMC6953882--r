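# Small fixture builders shared across test files.

tiny_config <- function(..., seed = 1L) {
  defaults <- list(n_lines = 80, n_snps = 300, n_te = 60, n_families = 8,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# a geno_matrix built directly from a 0/1 matrix (no simulation)
toy_geno <- function(G, chrom = NULL, pos = NULL) {
  n <- nrow(G); m <- ncol(G)
  if (is.null(rownames(G))) rownames(G) <- sprintf("L%03d", seq_len(n))
  if (is.null(colnames(G))) colnames(G) <- sprintf("s%03d", seq_len(m))
  f <- colMeans(G, na.rm = TRUE)
  map <- data.frame(snp = colnames(G),
                    chrom = if (is.null(chrom)) rep(1L, m) else chrom,
                    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
                    maf = pmin(f, 1 - f), label = NA_character_,
                    stringsAsFactors = FALSE)
  chhscan:::new_geno_matrix(G, map)
}

# haploid columns with exact haplotype counts n_AB, n_Ab, n_aB, n_ab
toy_haplotypes <- function(n_AB, n_Ab, n_aB, n_ab) {
  a <- c(rep(1, n_AB), rep(1, n_Ab), rep(0, n_aB), rep(0, n_ab))
  b <- c(rep(1, n_AB), rep(0, n_Ab), rep(1, n_aB), rep(0, n_ab))
  list(a = a, b = b)
}

rand_index <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2)) - a
  c_ <- sum(choose(colSums(tab), 2)) - a
  d <- choose(n, 2) - a - b - c_
  (a + d) / choose(n, 2)
}

make_matched_panel <- function(n = 400, n_null = 300, p = 0.2, seed = 1,
                               depletion = 1) {
  # target on chr1, partner on chr2, null SNPs on chr3 with exactly the
  # partner's MAF (independent permutations of a fixed column)
  set.seed(seed)
  k <- round(n * p)
  target <- sample(c(rep(1, k), rep(0, n - k)))
  if (depletion == 1) {
    partner <- sample(c(rep(1, k), rep(0, n - k)))
  } else {
    # force the double-carrier haplotype to `depletion` x independence
    n11 <- max(0L, round(depletion * k * k / n))
    partner <- integer(n)
    partner[sample(which(target == 1), n11)] <- 1
    partner[sample(which(target == 0), k - n11)] <- 1
  }
  base <- c(rep(1L, k), rep(0L, n - k))
  nulls <- vapply(seq_len(n_null), function(i) sample(base), integer(n))
  G <- cbind(target = target, partner = partner, nulls)
  colnames(G) <- c("target", "partner", sprintf("null%03d", seq_len(n_null)))
  toy_geno(G, chrom = c(1L, 2L, rep(3L, n_null)))
}
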
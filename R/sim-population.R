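#' Simulate a structured inbred-line panel
#'
#' Generates haploid-coded (0/1) genotypes for `n_lines` inbred lines.
#' Background SNPs follow a Balding-Nichols model: an ancestral frequency is
#' drawn per SNP, subpopulation frequencies are Beta-distributed around it
#' with divergence `fst`, and lines carry Bernoulli draws from their
#' subpopulation's frequency.  Causal SNPs from `config$causal_spec` are
#' placed at their stated positions with carriage probability following a
#' logistic allele-frequency gradient in longitude; alleles sharing a
#' `locus` are mutually exclusive (at most one alternative allele per line).
#' Monomorphic background SNPs (possible at small `n_lines`) are dropped.
#'
#' Longitude is drawn from a Europe-heavy two-block mixture inside
#' `config$lon_range` and is independent of subpopulation, so geography and
#' genetic structure are decoupled unless a causal cline couples them.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with elements `geno` (a `geno_matrix`: list of `G`, the
#'   lines-by-SNPs 0/1 matrix, and `map`, the per-SNP table with `snp`,
#'   `chrom`, `pos`, `maf`, `label`) and `meta` (per-line `line_id`,
#'   `longitude`, `latitude`, `subpop`).
#' @export
simulate_population <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  n <- config$n_lines
  line_id <- sprintf("L%04d", seq_len(n))

  ## geography: western/European block plus an eastern block
  lo <- config$lon_range[1]; hi <- config$lon_range[2]
  west_hi <- lo + 0.56 * (hi - lo)      # default [-25,100] -> 45
  east_lo <- lo + 0.64 * (hi - lo)      # default [-25,100] -> 55
  east <- stats::runif(n) < config$east_fraction
  longitude <- ifelse(east,
                      stats::runif(n, east_lo, hi),
                      stats::runif(n, max(lo, -20), west_hi))
  latitude <- stats::runif(n, 40, 65)
  subpop <- sprintf("pop%d", sample.int(config$n_subpop, n, replace = TRUE))
  meta <- data.frame(line_id = line_id, longitude = longitude,
                     latitude = latitude, subpop = subpop,
                     stringsAsFactors = FALSE)

  ## background SNPs: Balding-Nichols subpopulation frequencies
  m <- config$n_snps
  p0 <- stats::runif(m, 0.05, 0.5)
  F <- config$fst
  if (F > 0) {
    a <- p0 * (1 - F) / F
    b <- (1 - p0) * (1 - F) / F
    pop_freq <- vapply(seq_len(config$n_subpop),
                       function(k) stats::rbeta(m, a, b),
                       numeric(m))                      # m x n_subpop
  } else {
    pop_freq <- matrix(p0, m, config$n_subpop)
  }
  pop_idx <- as.integer(factor(subpop, levels = sprintf("pop%d", seq_len(config$n_subpop))))
  G <- matrix(stats::rbinom(n * m, 1L,
                            t(pop_freq[, pop_idx, drop = FALSE])),
              nrow = n, ncol = m)

  chrom <- sort(sample.int(config$n_chrom, m, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(config$chrom_length, length(ix)))), use.names = FALSE)
  ## anc_freq records the ancestral sampling frequency of background SNPs
  ## (NA for causal SNPs), so generator calibration is testable
  map <- data.frame(chrom = chrom, pos = pos, label = NA_character_,
                    anc_freq = p0, stringsAsFactors = FALSE)

  ## causal SNPs with logistic longitude clines
  cs <- config$causal_spec
  if (nrow(cs) > 0) {
    s <- (longitude - mean(config$lon_range)) / (diff(config$lon_range) / 2)
    carriage <- matrix(0L, n, nrow(cs))
    for (lc in unique(cs$locus)) {
      rows <- which(cs$locus == lc)
      q <- vapply(rows, function(r)
        cline_prob(s, cs$cline_slope[r], cs$maf[r], cs$label[r]), numeric(n))
      if (any(rowSums(q) > 0.999))
        stop("causal allele frequencies at locus ", lc, " exceed 1")
      carriage[, rows] <- draw_exclusive(q, cs$maf[rows], cs$label[rows],
                                         n_lines = n)
    }
    G <- cbind(G, carriage)
    map <- rbind(map, data.frame(chrom = cs$chrom, pos = cs$pos,
                                 label = cs$label, anc_freq = NA_real_,
                                 stringsAsFactors = FALSE))
  }

  ## order by genome position, drop duplicated positions and monomorphic SNPs
  o <- order(map$chrom, map$pos)
  G <- G[, o, drop = FALSE]; map <- map[o, , drop = FALSE]
  dup <- duplicated(map[c("chrom", "pos")]) & is.na(map$label)
  f <- colMeans(G)
  keep <- !dup & f > 0 & f < 1
  G <- G[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]

  map$snp <- sprintf("snp_%d_%d", map$chrom, map$pos)
  map$maf <- pmin(colMeans(G), 1 - colMeans(G))
  rownames(G) <- line_id
  colnames(G) <- map$snp
  geno <- new_geno_matrix(G, map[c("snp", "chrom", "pos", "maf", "label",
                                   "anc_freq")])
  list(geno = geno, meta = meta)
}

## carriage probability along the scaled longitude s in [-1, 1]; the
## logistic intercept is solved so the mean frequency over the sampled
## panel equals the target MAF
cline_prob <- function(s, slope, maf, label) {
  if (slope == 0) return(rep(maf, length(s)))
  fn <- function(a) mean(stats::plogis(a + slope * s)) - maf
  a <- tryCatch(stats::uniroot(fn, c(-50, 50))$root,
                error = function(e) stop("requested MAF unreachable for causal locus ",
                                         label, call. = FALSE))
  stats::plogis(a + slope * s)
}

## draw mutually exclusive allele carriage; realized MAF must land within
## +/-20% relative of the target (redrawn up to 50 times, then error)
draw_exclusive <- function(q, target_maf, labels, n_lines) {
  k <- ncol(q)
  for (try in 1:50) {
    u <- stats::runif(n_lines)
    cum <- if (k == 1) cbind(0, q) else cbind(0, t(apply(q, 1, cumsum)))
    out <- vapply(seq_len(k), function(j)
      as.integer(u >= cum[, j] & u < cum[, j + 1]), integer(n_lines))
    realized <- colMeans(out)
    ok <- abs(realized - target_maf) <= 0.2 * target_maf & realized > 0
    if (all(ok)) return(out)
  }
  bad <- labels[!ok][1]
  stop("requested MAF unreachable at given n_lines for causal locus ", bad,
       call. = FALSE)
}

new_geno_matrix <- function(G, map) {
  stopifnot(is.matrix(G), nrow(map) == ncol(G))
  structure(list(G = G, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$G), "lines x", ncol(x$G), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  lab <- x$map$label[!is.na(x$map$label)]
  if (length(lab)) cat("causal labels:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

## resolve a SNP given as column index, snp id, causal label or "chr:pos"
snp_column <- function(geno, snp) {
  map <- geno$map
  if (is.numeric(snp)) return(as.integer(snp))
  i <- match(snp, map$snp)
  if (is.na(i)) i <- match(snp, map$label)
  if (is.na(i) && grepl(":", snp)) {
    parts <- strsplit(snp, ":", fixed = TRUE)[[1]]
    i <- which(map$chrom == as.integer(parts[1]) & map$pos == as.integer(parts[2]))
    if (length(i) != 1) i <- NA_integer_
  }
  if (is.na(i)) stop("SNP not found: ", snp)
  i
}
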
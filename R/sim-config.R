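#' Default planted causal architecture
#'
#' Three trans-acting causal SNPs at two loci, mirroring the qualitative
#' architecture the pipeline is built to detect:
#'
#' * `trans_rddm` -- an eastern allele (steep logistic longitude cline) that
#'   decreases methylation of RdDM-class TEs and, more weakly, of CMT2-class
#'   TEs (a cross-class effect acting over the whole element).
#' * `cmt2_minus` / `cmt2_plus` -- two mutually exclusive alleles of one
#'   locus with opposite effects restricted to CMT2-class TEs.  The negative
#'   allele is western; its cline slope is chosen so that, together with the
#'   flat positive allele, the expected longitudinal gradient of CMT2-class
#'   methylation is zero (compensating geography).
#'
#' Effect sizes are on the methylation-level scale (difference in latent
#' mCHH level per copy of the alternative allele).
#'
#' @return A data.frame with one row per causal allele; columns `label`,
#'   `locus` (alleles sharing a locus are mutually exclusive), `chrom`,
#'   `pos`, `target_class`, `effect`, `cross_class`, `cross_effect`, `maf`
#'   and `cline_slope` (slope of the logistic allele-frequency gradient on
#'   longitude scaled to `[-1, 1]`; 0 = no cline).
#' @export
default_causal_spec <- function() {
  data.frame(
    label        = c("trans_rddm", "cmt2_minus", "cmt2_plus"),
    locus        = c("locus_rddm", "locus_cmt2", "locus_cmt2"),
    chrom        = c(2L, 4L, 4L),
    pos          = c(16719071L, 10417744L, 10422486L),
    target_class = c("rddm", "cmt2", "cmt2"),
    effect       = c(-0.05, -0.05, 0.04),
    cross_class  = c("cmt2", NA, NA),
    cross_effect = c(-0.04, 0, 0),
    maf          = c(0.09, 0.237, 0.20),
    cline_slope  = c(6, -1.9191, 0),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic panel generators
#'
#' Bundles every tunable of the synthetic-data module.  The defaults are the
#' study conditions used throughout the package's tests: a 500-line inbred
#' panel with three subpopulations, 5,000 genome-wide SNPs on five
#' chromosomes, 400 common TEs in 30 families split 40/40/20 between
#' RdDM-like, CMT2-like and untargeted classes, beta-binomial read noise at
#' mean depth 40, and the planted architecture of [default_causal_spec()].
#'
#' @param n_lines Number of inbred lines (haploid-coded; >= 4).
#' @param n_snps Number of background SNPs genome-wide.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bp (all chromosomes equal).
#' @param n_te Number of TEs (>= 10).
#' @param n_families Number of TE families.
#' @param class_fractions Named proportions of TEs assigned to the
#'   `rddm` / `cmt2` / `untargeted` classes; must sum to 1.
#' @param causal_spec Data.frame as returned by [default_causal_spec()].
#' @param read_depth_mean Mean sequencing depth per TE per line.
#' @param overdispersion Beta-binomial overdispersion rho in (0, 1); the
#'   variance inflation of a depth-d count is `1 + (d - 1) * rho`.
#' @param h2_background Fraction of line-level variance that is polygenic
#'   (covariance proportional to IBS kinship), in `[0, 1]`.
#' @param sd_line Standard deviation of line-level methylation noise
#'   (shared across TEs of a class within a line).
#' @param sd_te Standard deviation of independent per-line-per-TE noise.
#' @param sd_te_offset Standard deviation of the per-TE baseline offset
#'   (constant across lines).
#' @param baseline Named per-class latent methylation baselines.
#' @param n_subpop Number of subpopulations.
#' @param fst Balding-Nichols divergence parameter in `[0, 1)`; 0 gives a
#'   single panmictic frequency per SNP.
#' @param lon_range Longitude window of the panel (degrees).
#' @param east_fraction Fraction of lines drawn from the eastern longitude
#'   block (the remainder is the western/European block).
#' @param emit_bins If `TRUE`, [simulate_methylomes()] also emits 60-bin
#'   positional counts (20 upstream / 20 body / 20 downstream) per TE.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_lines = 500L, n_snps = 5000L, n_chrom = 5L,
                       chrom_length = 30e6, n_te = 400L, n_families = 30L,
                       class_fractions = c(rddm = 0.4, cmt2 = 0.4, untargeted = 0.2),
                       causal_spec = default_causal_spec(),
                       read_depth_mean = 40, overdispersion = 0.1,
                       h2_background = 0.3, sd_line = 0.055, sd_te = 0.04,
                       sd_te_offset = 0.02,
                       baseline = c(rddm = 0.15, cmt2 = 0.25, untargeted = 0.12),
                       n_subpop = 3L, fst = 0.1,
                       lon_range = c(-25, 100), east_fraction = 0.2,
                       emit_bins = FALSE, seed = 1L) {
  cfg <- list(
    n_lines = as.integer(n_lines), n_snps = as.integer(n_snps),
    n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
    n_te = as.integer(n_te), n_families = as.integer(n_families),
    class_fractions = class_fractions, causal_spec = causal_spec,
    read_depth_mean = read_depth_mean, overdispersion = overdispersion,
    h2_background = h2_background, sd_line = sd_line, sd_te = sd_te,
    sd_te_offset = sd_te_offset, baseline = baseline,
    n_subpop = as.integer(n_subpop), fst = fst, lon_range = lon_range,
    east_fraction = east_fraction, emit_bins = isTRUE(emit_bins),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_lines >= 4L, cfg$n_snps >= 1L, cfg$n_chrom >= 1L,
            cfg$n_te >= 1L, cfg$n_families >= 1L)
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (!all(c("rddm", "cmt2", "untargeted") %in% names(cfg$class_fractions)))
    stop("class_fractions must be named rddm/cmt2/untargeted")
  cs <- cfg$causal_spec
  if (nrow(cs) > 0) {
    if (any(cs$maf <= 0 | cs$maf > 0.5))
      stop("causal MAFs must lie in (0, 0.5]")
    if (any(!is.finite(cs$effect)) || any(!is.finite(cs$cross_effect)))
      stop("causal effect sizes must be finite")
    if (any(cs$chrom > cfg$n_chrom))
      stop("causal chromosome index exceeds n_chrom")
    if (any(cs$pos > cfg$chrom_length))
      stop("causal position exceeds chrom_length")
  }
  if (cfg$overdispersion <= 0 || cfg$overdispersion >= 1)
    stop("overdispersion must be in (0, 1)")
  if (cfg$h2_background < 0 || cfg$h2_background > 1)
    stop("h2_background must be in [0, 1]")
  if (cfg$fst < 0 || cfg$fst >= 1) stop("fst must be in [0, 1)")
  invisible(cfg)
}

#' Read or write a simulation config as YAML
#'
#' @param path File path.
#' @param config A `sim_config` object.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$causal_spec))
    raw$causal_spec <- as.data.frame(raw$causal_spec, stringsAsFactors = FALSE)
  for (nm in c("class_fractions", "baseline"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$causal_spec <- as.list(x$causal_spec)
  x$class_fractions <- as.list(x$class_fractions)
  x$baseline <- as.list(x$baseline)
  yaml::write_yaml(x, path)
  invisible(path)
}
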
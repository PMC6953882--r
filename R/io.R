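## Readers/writers for the pipeline's on-disk formats.  All tabular files
## are TSV with a single '#'-prefixed schema header line; genotypes are
## also emitted as a minimal haploid VCF.

write_schema_tsv <- function(df, path, schema = paste(names(df), collapse = "\t")) {
  con <- file(path, "w")
  writeLines(paste0("# ", schema), con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

read_schema_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", skip = 1L, header = TRUE))
}

#' Write genotypes as a minimal VCF
#'
#' Emits CHROM/POS/ID/REF=A/ALT=T and one haploid GT column per line.
#'
#' @param genotypes A `geno_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  map <- genotypes$map
  gt <- t(genotypes$G)
  gt[is.na(gt)] <- "."
  body <- cbind(map$chrom, map$pos, map$snp, "A", "T", ".", "PASS", ".",
                "GT", gt)
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=chhscan-simulate",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes$G)),
                     collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Read genotypes from VCF or TSV
#'
#' VCF is parsed with the vcfR package (haploid or homozygous-diploid GT
#' fields become 0/1); the TSV dialect is the matrix written by
#' [write_genotypes_tsv()].
#'
#' @param path Input path ending in `.vcf`/`.vcf.gz` or `.tsv`.
#' @return A `geno_matrix`.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    first <- substr(gt, 1, 1)
    G <- t(matrix(match(first, c("0", "1")) - 1L,
                  nrow = nrow(gt), dimnames = dimnames(gt)))
    map <- data.frame(snp = rownames(gt),
                      chrom = as.integer(v@fix[, "CHROM"]),
                      pos = as.integer(v@fix[, "POS"]),
                      stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(data.table::fread(path, sep = "\t", skip = 1L))
    map <- df[c("snp", "chrom", "pos")]
    G <- t(as.matrix(df[, -(1:3), drop = FALSE]))
    colnames(G) <- map$snp
  }
  f <- colMeans(G, na.rm = TRUE)
  map$maf <- pmin(f, 1 - f)
  map$label <- NA_character_
  new_geno_matrix(G, map)
}

#' Write genotypes as a TSV matrix (SNPs as rows, lines as columns)
#'
#' @inheritParams write_genotypes_vcf
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(snp = genotypes$map$snp, chrom = genotypes$map$chrom,
                   pos = genotypes$map$pos, t(genotypes$G),
                   check.names = FALSE)
  write_schema_tsv(df, path, "snp\tchrom\tpos\t<one 0/1 column per line>")
}

#' Write/read methylation counts as allc-style TSV
#'
#' Long format: one row per (line, TE) with methylated and total read
#' counts.
#'
#' @param counts A `methyl_counts` object.
#' @param path File path.
#' @return `write_methyl_counts()` returns `path`; `read_methyl_counts()`
#'   a `methyl_counts` object (without positional bins).
#' @export
write_methyl_counts <- function(counts, path) {
  long <- data.frame(
    line_id = rep(rownames(counts$mc), times = ncol(counts$mc)),
    te_id = rep(colnames(counts$mc), each = nrow(counts$mc)),
    mc_count = as.integer(counts$mc),
    total_count = as.integer(counts$total))
  write_schema_tsv(long, path)
}

#' @rdname write_methyl_counts
#' @param annotation Optional TE annotation to attach.
#' @export
read_methyl_counts <- function(path, annotation = NULL) {
  long <- read_schema_tsv(path)
  lines <- unique(long$line_id); tes <- unique(long$te_id)
  mc <- matrix(NA_integer_, length(lines), length(tes),
               dimnames = list(lines, tes))
  tot <- mc
  li <- match(long$line_id, lines); ti <- match(long$te_id, tes)
  mc[cbind(li, ti)] <- long$mc_count
  tot[cbind(li, ti)] <- long$total_count
  if (any(mc > tot, na.rm = TRUE)) stop("mc_count exceeds total_count")
  structure(list(mc = mc, total = tot, bins = NULL,
                 annotation = annotation, truth = NULL),
            class = "methyl_counts")
}

#' Write/read a TE annotation as BED6+3
#'
#' Columns: chrom, start, end, name (te_id), score (length), strand,
#' family, superfamily, class.
#'
#' @param annotation TE annotation data.frame.
#' @param path File path.
#' @export
write_te_annotation <- function(annotation, path) {
  bed <- data.frame(chrom = annotation$chrom, start = annotation$start,
                    end = annotation$end, name = annotation$te_id,
                    score = annotation$length, strand = ".",
                    family = annotation$family,
                    superfamily = annotation$superfamily,
                    class = annotation$class)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_te_annotation
#' @export
read_te_annotation <- function(path) {
  bed <- as.data.frame(data.table::fread(
    path, sep = "\t",
    col.names = c("chrom", "start", "end", "name", "score", "strand",
                  "family", "superfamily", "class")))
  if (any(bed$start > bed$end)) stop("BED interval with start > end")
  data.frame(te_id = bed$name, chrom = bed$chrom, start = bed$start,
             end = bed$end, family = bed$family,
             superfamily = bed$superfamily, class = bed$class,
             length = bed$end - bed$start,
             pericentromeric = NA, stringsAsFactors = FALSE)
}

#' Export a family dendrogram as Newick
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
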
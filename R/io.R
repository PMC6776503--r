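# Readers and writers for the standard formats the pipeline exchanges:
# VCF genotypes, summary-statistic / phenotype / endophenotype TSVs, BED
# regions, GMT gene sets, JSON truth records and manifests.

#' Write genotypes to a VCF file
#'
#' Minimal VCFv4.2 with a GT field. The counted allele (a1) is written as
#' ALT and the other allele as REF, so the dosage equals the ALT allele
#' count; missing calls become "./.".
#'
#' @param geno a \code{genotype_matrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  gt_codes <- c("0/0", "0/1", "1/1")
  dos <- t(geno$dosages)  # SNPs x individuals
  gt <- matrix("./.", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_codes[dos[ok] + 1L]
  body <- paste(geno$snp_meta$chr, geno$snp_meta$bp, geno$snp_meta$snp,
                geno$snp_meta$a2, geno$snp_meta$a1, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=prsmed",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t"),
    body), con)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses GT calls into an ALT-allele dosage matrix; the counted allele (a1)
#' is the ALT allele.
#'
#' @param path VCF file (plain or gzipped).
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # biallelic GT lookup (phased or unphased); anything else stays missing
  key <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dos <- matrix(key[gt], nrow(gt), ncol(gt))
  dos <- t(dos)  # individuals x SNPs
  fx <- vcfR::getFIX(v)
  meta <- data.frame(
    snp = fx[, "ID"], chr = as.integer(fx[, "CHROM"]),
    bp = as.integer(fx[, "POS"]), a1 = fx[, "ALT"], a2 = fx[, "REF"],
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, meta, colnames(gt))
}

#' Write / read GWAS summary statistics TSV
#'
#' Columns SNP, CHR, BP, A1, A2, BETA, SE, P. The hidden simulation truth
#' column (beta_true), when present, is dropped on write.
#'
#' @param stats a \code{summary_stats} table.
#' @param path file path.
#' @return \code{path} (write) or a \code{summary_stats} (read).
#' @export
write_sumstats <- function(stats, path) {
  df <- data.frame(SNP = stats$snp, CHR = stats$chr, BP = stats$bp,
                   A1 = stats$a1, A2 = stats$a2, BETA = stats$beta,
                   SE = stats$se, P = stats$p)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  summary_stats(df[, c("snp", "chr", "bp", "a1", "a2", "beta", "se", "p")])
}

#' Write / read a plain TSV table
#'
#' @param tab data.frame; row names are written as a leading column when
#'   \code{rownames_as} is given.
#' @param path file path.
#' @param rownames_as optional column name for row names.
#' @return \code{path} (write) or a data.frame (read).
#' @export
write_tsv <- function(tab, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    tab <- cbind(setNames(data.frame(rownames(tab), stringsAsFactors = FALSE),
                          rownames_as), tab)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read / write BED regions
#'
#' BED is 0-based half-open on disk; intervals are converted to the 1-based
#' inclusive convention used internally.
#'
#' @param path BED file (chrom, start, end, optional name).
#' @return data.frame chr, start, end, label (1-based inclusive).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least 3 columns", call. = FALSE)
  out <- data.frame(
    chr = suppressWarnings(as.integer(sub("^chr", "", df[[1]]))),
    start = df[[2]] + 1L, end = df[[3]],
    label = if (ncol(df) >= 4) df[[4]] else "",
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop("malformed BED interval", call. = FALSE)
  class(out) <- c("genomic_region", "data.frame")
  out
}

#' @rdname read_bed
#' @param regions a \code{genomic_region} table (1-based inclusive).
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(paste0("chr", regions$chr), regions$start - 1L,
                   regions$end, regions$label)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (term, description, genes...).
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write an object as pretty JSON
#'
#' @param x list-like object (vectors are auto-unboxed when length 1).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a consensus network as edge TSV and DOT
#'
#' @param net a \code{bnetwork}.
#' @param tsv_path edge-list TSV output (parent, child, frequency, sign,
#'   variance_explained, p).
#' @param dot_path optional Graphviz DOT output.
#' @return \code{tsv_path}, invisibly.
#' @export
write_bnetwork <- function(net, tsv_path, dot_path = NULL) {
  stopifnot(inherits(net, "bnetwork"))
  write_tsv(net$edges, tsv_path)
  if (!is.null(dot_path)) {
    lines <- c("digraph bnetwork {")
    for (nd in net$nodes) lines <- c(lines, sprintf('  "%s";', nd))
    if (nrow(net$edges)) {
      lines <- c(lines, sprintf(
        '  "%s" -> "%s" [label="%s, R2=%.2f, p=%.2g (%.2f)"];',
        net$edges$parent, net$edges$child,
        ifelse(net$edges$sign > 0, "+", "-"),
        net$edges$variance_explained, net$edges$p, net$edges$frequency))
    }
    writeLines(c(lines, "}"), dot_path)
  }
  invisible(tsv_path)
}
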
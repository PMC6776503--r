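# Polygenic risk scoring from GWAS summary statistics: allele harmonization,
# sample-overlap adjustment by inverse-variance subtraction, greedy LD
# clumping, and p-value-threshold scoring with locus exclusion.

#' Construct / validate a summary-statistics table
#'
#' @param df data.frame with columns snp, chr, bp, a1 (effect allele), a2,
#'   beta (per-allele effect, beta or log-OR), se, p.
#' @return the validated data.frame, classed \code{summary_stats}.
#' @export
summary_stats <- function(df) {
  need <- c("snp", "chr", "bp", "a1", "a2", "beta", "se", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("summary stats missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$snp)) stop("SNP ids must be unique", call. = FALSE)
  if (any(df$se < 0, na.rm = TRUE)) stop("se must be >= 0", call. = FALSE)
  if (any(df$p <= 0 | df$p > 1, na.rm = TRUE)) {
    stop("p must lie in (0, 1]", call. = FALSE)
  }
  bad <- !(df$a1 %in% c("A", "C", "G", "T")) | !(df$a2 %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("alleles must be A/C/G/T", call. = FALSE)
  class(df) <- c("summary_stats", "data.frame")
  df
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics to a genotype panel
#'
#' Restricts the statistics to SNPs present in the panel, re-orients effects
#' to the panel's counted allele (negating beta and swapping alleles when the
#' panel tracks the other allele), drops strand-ambiguous (A/T, C/G) SNPs,
#' and drops SNPs whose allele pairs do not match the panel. Counts of each
#' disposition are logged.
#'
#' @param stats a \code{summary_stats} table.
#' @param geno a \code{genotype_matrix}.
#' @return harmonized \code{summary_stats} whose \code{a1} equals the panel's
#'   counted allele for every SNP.
#' @export
harmonize <- function(stats, geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  stats <- summary_stats(stats)
  idx <- match(stats$snp, geno$snp_meta$snp)
  present <- !is.na(idx)
  st <- stats[present, , drop = FALSE]
  gm <- geno$snp_meta[idx[present], , drop = FALSE]

  ambiguous <- is_strand_ambiguous(st$a1, st$a2)
  same <- st$a1 == gm$a1 & st$a2 == gm$a2
  flipped <- st$a1 == gm$a2 & st$a2 == gm$a1
  keep <- !ambiguous & (same | flipped)

  out <- st[keep, , drop = FALSE]
  flip <- flipped[keep]
  out$beta[flip] <- -out$beta[flip]
  tmp <- out$a1[flip]
  out$a1[flip] <- out$a2[flip]
  out$a2[flip] <- tmp
  # adopt panel coordinates so downstream windows agree with the panel
  gidx <- match(out$snp, geno$snp_meta$snp)
  out$chr <- geno$snp_meta$chr[gidx]
  out$bp <- geno$snp_meta$bp[gidx]

  log_msg("prscore",
          "harmonize: %d input, %d absent from panel, %d ambiguous, %d allele-mismatch, %d flipped, %d retained",
          nrow(stats), sum(!present), sum(ambiguous),
          sum(!ambiguous & !(same | flipped)), sum(flip), nrow(out))
  if (nrow(out) == 0) stop("no SNPs survived harmonization", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Remove a cohort's contribution from meta-analysis summary statistics
#'
#' Inverse-variance subtraction: with per-SNP precisions \code{w = 1/se^2},
#' \code{beta_adj = (w_m*beta_m - w_o*beta_o) / (w_m - w_o)} and
#' \code{se_adj = (w_m - w_o)^(-1/2)}; p-values are recomputed from the Wald
#' statistic. This exactly inverts an inverse-variance-weighted meta-analysis
#' that included the overlapping cohort. SNPs absent from \code{overlap} pass
#' through unchanged.
#'
#' @param meta \code{summary_stats} of the full meta-analysis.
#' @param overlap \code{summary_stats} of the overlapping cohort's own GWAS.
#' @param on_invalid what to do when a SNP's meta precision does not exceed
#'   its overlap precision: \code{"drop"} (default, with a warning) or
#'   \code{"error"}.
#' @return adjusted \code{summary_stats}.
#' @export
adjust_overlap <- function(meta, overlap, on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  meta <- summary_stats(meta)
  overlap <- summary_stats(overlap)
  j <- match(meta$snp, overlap$snp)
  hit <- which(!is.na(j))
  if (!length(hit)) return(meta)

  w_m <- 1 / meta$se[hit]^2
  w_o <- 1 / overlap$se[j[hit]]^2
  bad <- w_m <= w_o
  if (any(bad)) {
    msg <- sprintf("%d SNP(s) with meta precision <= overlap precision", sum(bad))
    if (on_invalid == "error") stop(msg, call. = FALSE)
    warning(msg, "; dropped")
  }
  b_adj <- (w_m * meta$beta[hit] - w_o * overlap$beta[j[hit]]) / (w_m - w_o)
  se_adj <- (w_m - w_o)^(-0.5)

  out <- meta
  out$beta[hit] <- b_adj
  out$se[hit] <- se_adj
  out$p[hit] <- pmax(2 * pnorm(-abs(b_adj / se_adj)), 1e-300)
  drop <- hit[bad]
  if (length(drop)) out <- out[-drop, , drop = FALSE]
  rownames(out) <- NULL
  summary_stats(out)
}

# deterministic total order for clumping: p ascending, then chromosome,
# position, id
clump_order <- function(stats) {
  order(stats$p, stats$chr, stats$bp, stats$snp)
}

#' Greedy LD clumping
#'
#' Sorts SNPs by p-value and repeatedly takes the most significant remaining
#' SNP as an index, removing every SNP on the same chromosome within
#' \code{window_kb} whose squared dosage correlation with the index exceeds
#' \code{r2_threshold}. LD is estimated in the scoring cohort itself.
#' Defaults follow common practice for Alzheimer's PRS construction
#' (r^2 > 0.1 within 2000 kb).
#'
#' @param stats harmonized \code{summary_stats}; every SNP must be present in
#'   \code{geno}.
#' @param geno a \code{genotype_matrix} supplying the LD estimates.
#' @param r2_threshold squared-correlation threshold above which a neighbor
#'   is removed.
#' @param window_kb window half-width in kilobases.
#' @return the retained \code{summary_stats}, in the deterministic clumping
#'   order (p ascending; ties by chromosome, position, id).
#' @export
ld_clump <- function(stats, geno, r2_threshold = 0.1, window_kb = 2000) {
  stopifnot(inherits(geno, "genotype_matrix"))
  stats <- summary_stats(stats)
  gi <- match(stats$snp, geno$snp_meta$snp)
  if (anyNA(gi)) {
    stop("SNP(s) absent from genotype panel (harmonize first): ",
         paste(head(stats$snp[is.na(gi)], 5), collapse = ", "), call. = FALSE)
  }
  ord <- clump_order(stats)
  st <- stats[ord, , drop = FALSE]
  dos <- impute_mean_dosage(geno$dosages[, match(st$snp, geno$snp_meta$snp),
                                         drop = FALSE])
  m <- nrow(st)
  alive <- rep(TRUE, m)
  keep <- logical(m)
  win <- window_kb * 1000
  for (i in seq_len(m)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & st$chr == st$chr[i] & abs(st$bp - st$bp[i]) <= win)
    if (!length(cand)) next
    r <- suppressWarnings(as.vector(cor(dos[, i], dos[, cand, drop = FALSE])))
    r[is.na(r)] <- 0
    alive[cand[r^2 > r2_threshold]] <- FALSE
  }
  out <- st[keep, , drop = FALSE]
  log_msg("prscore", "clump: %d -> %d SNPs (r2 > %g within %g kb removed)",
          m, nrow(out), r2_threshold, window_kb)
  rownames(out) <- NULL
  out
}

#' Genomic region table
#'
#' @param chr chromosome, \code{start}/\code{end} 1-based inclusive bounds,
#'   \code{label} free text.
#' @param start,end,label see above.
#' @return data.frame of class \code{genomic_region}.
#' @export
genomic_region <- function(chr, start, end, label = "") {
  if (any(start > end)) stop("region start must be <= end", call. = FALSE)
  structure(data.frame(chr = chr, start = start, end = end, label = label,
                       stringsAsFactors = FALSE),
            class = c("genomic_region", "data.frame"))
}

in_regions <- function(chr, bp, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, length(chr)))
  hit <- rep(FALSE, length(chr))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chr == regions$chr[i] & bp >= regions$start[i] &
                    bp <= regions$end[i])
  }
  hit
}

#' Compute polygenic risk scores over a p-value threshold series
#'
#' For each inclusion threshold t the score of individual i is the average of
#' the counted-allele dosages weighted by the summary-statistic effect over
#' the SNP set S(t) = {p <= t, outside \code{exclude}, inside
#' \code{restrict_to} if given}: \code{(1/|S|) * sum_j beta_j * dosage_ij}.
#' Missing genotypes are mean-imputed per SNP. Scores are also standardized
#' to mean 0 / SD 1 over the scored cohort.
#'
#' @param stats clumped, harmonized \code{summary_stats}.
#' @param geno a \code{genotype_matrix}.
#' @param p_thresholds inclusion thresholds; the conventional series up to 1.
#' @param exclude optional \code{genomic_region} table of loci to leave out
#'   (e.g. the ApoE/TOMM40 region).
#' @param restrict_to optional \code{genomic_region} table; when given, only
#'   SNPs inside it are scored (e.g. an ApoE/TOMM40-only score).
#' @param denominator \code{"snps"} divides by |S| (the default,
#'   weighted-average-per-SNP), \code{"alleles"} by 2|S|.
#' @return object of class \code{prs_result}: raw and standardized score
#'   matrices (individuals x thresholds), SNP counts used per threshold, and
#'   provenance.
#' @export
compute_prs <- function(stats, geno,
                        p_thresholds = c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1,
                                         0.5, 1.0),
                        exclude = NULL, restrict_to = NULL,
                        denominator = c("snps", "alleles")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(geno, "genotype_matrix"))
  stats <- summary_stats(stats)
  gi <- match(stats$snp, geno$snp_meta$snp)
  if (anyNA(gi)) stop("SNP(s) absent from genotype panel", call. = FALSE)

  usable <- !in_regions(stats$chr, stats$bp, exclude)
  if (!is.null(restrict_to)) {
    usable <- usable & in_regions(stats$chr, stats$bp, restrict_to)
  }
  dos <- impute_mean_dosage(geno$dosages)
  n <- nrow(dos)
  tl <- as.character(p_thresholds)
  raw <- matrix(NA_real_, n, length(p_thresholds),
                dimnames = list(geno$sample_ids, tl))
  std <- raw
  nsnp <- setNames(integer(length(p_thresholds)), tl)
  for (k in seq_along(p_thresholds)) {
    sel <- which(usable & stats$p <= p_thresholds[k])
    nsnp[k] <- length(sel)
    if (!length(sel)) {
      warning(sprintf("no SNPs pass threshold %g; scores set missing",
                      p_thresholds[k]))
      next
    }
    denom <- if (denominator == "snps") length(sel) else 2 * length(sel)
    sc <- as.vector(dos[, gi[sel], drop = FALSE] %*% stats$beta[sel]) / denom
    raw[, k] <- sc
    s <- sd(sc)
    if (is.na(s) || s == 0) {
      warning(sprintf("threshold %g: zero score variance; standardized scores set missing",
                      p_thresholds[k]))
    } else {
      std[, k] <- (sc - mean(sc)) / s
    }
  }
  structure(list(raw = raw, standardized = std, thresholds = p_thresholds,
                 n_snps_used = nsnp, excluded = exclude,
                 restricted_to = restrict_to, denominator = denominator,
                 sample_ids = geno$sample_ids),
            class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("prs_result: %d individuals, %d threshold(s)\n",
              length(x$sample_ids), length(x$thresholds)))
  print(data.frame(threshold = x$thresholds, n_snps = as.integer(x$n_snps_used)))
  invisible(x)
}

#' Extract one PRS vector from a \code{prs_result}
#'
#' @param prs a \code{prs_result}.
#' @param threshold which inclusion threshold (default: the largest computed,
#'   matching the conventional headline threshold of 0.5 when present).
#' @param standardized return the standardized (default) or raw score.
#' @return named numeric vector over individuals.
#' @export
prs_vector <- function(prs, threshold = NULL, standardized = TRUE) {
  stopifnot(inherits(prs, "prs_result"))
  if (is.null(threshold)) {
    threshold <- if (0.5 %in% prs$thresholds) 0.5 else max(prs$thresholds)
  }
  k <- match(as.character(threshold), colnames(prs$raw))
  if (is.na(k)) stop("threshold not present in prs_result", call. = FALSE)
  v <- if (standardized) prs$standardized[, k] else prs$raw[, k]
  setNames(v, prs$sample_ids)
}
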
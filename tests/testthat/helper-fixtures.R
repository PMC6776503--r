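# Shared fixture builders: tiny literal genotype panels and summary-stat
# tables for unit tests. All randomness in tests is locally seeded.

toy_geno <- function(dosages, chr = NULL, bp = NULL, a1 = NULL, a2 = NULL) {
  m <- ncol(dosages)
  genotype_matrix(
    dosages,
    data.frame(
      snp = sprintf("rs%03d", seq_len(m)),
      chr = if (is.null(chr)) rep(1L, m) else chr,
      bp = if (is.null(bp)) seq_len(m) * 1000L else bp,
      a1 = if (is.null(a1)) rep("A", m) else a1,
      a2 = if (is.null(a2)) rep("C", m) else a2,
      stringsAsFactors = FALSE
    ),
    sprintf("ind%03d", seq_len(nrow(dosages)))
  )
}

toy_stats <- function(m, beta = NULL, se = NULL, p = NULL, chr = NULL,
                      bp = NULL, a1 = NULL, a2 = NULL) {
  summary_stats(data.frame(
    snp = sprintf("rs%03d", seq_len(m)),
    chr = if (is.null(chr)) rep(1L, m) else chr,
    bp = if (is.null(bp)) seq_len(m) * 1000L else bp,
    a1 = if (is.null(a1)) rep("A", m) else a1,
    a2 = if (is.null(a2)) rep("C", m) else a2,
    beta = if (is.null(beta)) rep(0.1, m) else beta,
    se = if (is.null(se)) rep(0.05, m) else se,
    p = if (is.null(p)) rep(0.5, m) else p,
    stringsAsFactors = FALSE
  ))
}

random_panel <- function(n, m, seed, n_chr = 2L, maf = NULL) {
  set.seed(seed)
  maf <- if (is.null(maf)) runif(m, 0.1, 0.45) else rep(maf, length.out = m)
  # correlated pairs: half the SNPs copy a neighbor with flips
  dos <- sapply(maf, function(f) rbinom(n, 2, f))
  for (j in seq(2, m, by = 2)) {
    if (runif(1) < 0.5) {
      flip <- runif(n) < 0.15
      d <- dos[, j - 1]
      d[flip] <- rbinom(sum(flip), 2, maf[j])
      dos[, j] <- d
    }
  }
  chr <- 1L + (seq_len(m) - 1L) %% n_chr
  bp <- integer(m)
  for (c0 in seq_len(n_chr)) {
    idx <- which(chr == c0)
    bp[idx] <- seq_along(idx) * sample(c(50000L, 500000L), 1)
  }
  ord <- order(chr, bp)
  toy_geno(dos[, ord, drop = FALSE], chr = chr[ord], bp = bp[ord])
}

# independent brute-force clumping oracle: straight transcription of the
# greedy rule with no shared code with ld_clump
brute_clump <- function(stats, geno, r2_threshold, window_kb) {
  df <- as.data.frame(stats)
  df <- df[order(df$p, df$chr, df$bp, df$snp), ]
  dos <- geno$dosages[, match(df$snp, geno$snp_meta$snp), drop = FALSE]
  mu <- colMeans(dos, na.rm = TRUE)
  for (j in seq_len(ncol(dos))) dos[is.na(dos[, j]), j] <- mu[j]
  kept <- character(0)
  removed <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (removed[i]) next
    kept <- c(kept, df$snp[i])
    for (j in seq_len(nrow(df))) {
      if (i == j || removed[j]) next
      if (df$chr[j] == df$chr[i] &&
          abs(df$bp[j] - df$bp[i]) <= window_kb * 1000) {
        r <- suppressWarnings(cor(dos[, i], dos[, j]))
        if (!is.na(r) && r^2 > r2_threshold) removed[j] <- TRUE
      }
    }
    removed[i] <- TRUE
  }
  kept
}
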
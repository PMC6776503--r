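test_that("harmonize keeps matches, flips swapped alleles, drops ambiguous and mismatched", {
  dos <- matrix(c(0L, 1L, 2L, 1L), 1, 4)
  geno <- toy_geno(dos, a1 = c("G", "G", "A", "C"), a2 = c("A", "A", "T", "A"))
  st <- toy_stats(4, beta = c(0.3, 0.3, 0.3, 0.3),
                  a1 = c("G", "A", "A", "G"), a2 = c("A", "G", "T", "T"))
  h <- suppressMessages(harmonize(st, geno))
  # rs001: identity; rs002: flipped; rs003: A/T ambiguous; rs004: mismatch
  expect_equal(h$snp, c("rs001", "rs002"))
  expect_equal(h$beta, c(0.3, -0.3))
  expect_equal(h$a1, c("G", "G"))  # tracked allele after flip
})

test_that("harmonize errors when nothing survives", {
  geno <- toy_geno(matrix(0L, 1, 1), a1 = "A", a2 = "C")
  st <- toy_stats(1, a1 = "G", a2 = "T")
  expect_error(suppressMessages(harmonize(st, geno)), "no SNPs")
})

test_that("overlap adjustment has the right limits", {
  meta <- toy_stats(3, beta = c(0.2, -0.1, 0.4), se = c(0.02, 0.03, 0.05))
  # near-zero overlap precision: output ~ input
  ov <- meta
  ov$se <- rep(1e6, 3)
  adj <- adjust_overlap(meta, ov)
  expect_equal(adj$beta, meta$beta, tolerance = 1e-8)
  expect_equal(adj$se, meta$se, tolerance = 1e-6)
  # equal effects with half the precision: beta unchanged, se grows
  ov2 <- meta
  ov2$se <- meta$se * sqrt(2)
  adj2 <- adjust_overlap(meta, ov2)
  expect_equal(adj2$beta, meta$beta, tolerance = 1e-12)
})

test_that("overlap adjustment inverts inverse-variance meta-analysis", {
  set.seed(42)
  m <- 200
  s1 <- toy_stats(m, beta = rnorm(m, 0, 0.1), se = runif(m, 0.01, 0.1),
                  p = runif(m))
  s2 <- toy_stats(m, beta = rnorm(m, 0, 0.1), se = runif(m, 0.01, 0.1),
                  p = runif(m))
  w1 <- 1 / s1$se^2
  w2 <- 1 / s2$se^2
  combined <- s1
  combined$beta <- (w1 * s1$beta + w2 * s2$beta) / (w1 + w2)
  combined$se <- (w1 + w2)^-0.5
  combined$p <- 2 * pnorm(-abs(combined$beta / combined$se))
  back <- adjust_overlap(combined, s2)
  expect_equal(back$beta, s1$beta, tolerance = 1e-10)
  expect_equal(back$se, s1$se, tolerance = 1e-10)
})

test_that("invalid precision ordering is dropped or raised as configured", {
  meta <- toy_stats(2, se = c(0.1, 0.01))
  ov <- toy_stats(2, se = c(0.05, 0.02))  # first SNP: overlap more precise
  expect_warning(adj <- adjust_overlap(meta, ov), "precision")
  expect_equal(adj$snp, "rs002")
  expect_error(adjust_overlap(meta, ov, on_invalid = "error"), "precision")
})

test_that("clumping keeps the singleton and the more significant of a perfect pair", {
  dos1 <- matrix(sample(0:2, 50, TRUE), 50, 1)
  expect_equal(suppressMessages(
    ld_clump(toy_stats(1, p = 0.01), toy_geno(dos1), 0.1, 2000))$snp, "rs001")

  d <- sample(0:2, 80, TRUE)
  geno <- toy_geno(cbind(d, d), bp = c(1000L, 5000L))
  st <- toy_stats(2, p = c(1e-4, 1e-8), bp = c(1000L, 5000L))
  out <- suppressMessages(ld_clump(st, geno, 0.1, 2000))
  expect_equal(out$snp, "rs002")  # the p=1e-8 SNP wins
})

test_that("clumping matches the brute-force oracle on random panels", {
  for (s in 1:25) {
    m <- sample(10:60, 1)
    geno <- random_panel(n = 120, m = m, seed = 1000 + s)
    set.seed(2000 + s)
    st <- toy_stats(m, p = runif(m), chr = geno$snp_meta$chr,
                    bp = geno$snp_meta$bp)
    got <- suppressMessages(ld_clump(st, geno, 0.1, 2000))$snp
    want <- brute_clump(st, geno, 0.1, 2000)
    expect_identical(got, want)
  }
})

test_that("clumping is invariant to input row order", {
  geno <- random_panel(n = 100, m = 30, seed = 5)
  set.seed(6)
  st <- toy_stats(30, p = runif(30), chr = geno$snp_meta$chr,
                  bp = geno$snp_meta$bp)
  a <- suppressMessages(ld_clump(st, geno))
  perm <- st[sample(nrow(st)), ]
  b <- suppressMessages(ld_clump(summary_stats(perm), geno))
  expect_identical(a$snp, b$snp)
})

test_that("clumping refuses SNPs missing from the panel", {
  geno <- toy_geno(matrix(0:1, 2, 1))
  st <- toy_stats(2)
  expect_error(ld_clump(st, geno), "harmonize")
})

test_that("PRS arithmetic on a single SNP and degenerate weights", {
  geno <- toy_geno(matrix(c(0L, 1L, 2L), 3, 1))
  st <- toy_stats(1, beta = 1, p = 0.5)
  prs <- compute_prs(st, geno, p_thresholds = 1)
  expect_equal(unname(prs$raw[, 1]), c(0, 1, 2))
  expect_equal(unname(prs$standardized[, 1]), c(-1, 0, 1))

  st0 <- toy_stats(1, beta = 0, p = 0.5)
  expect_warning(prs0 <- compute_prs(st0, geno, p_thresholds = 1),
                 "zero score variance")
  expect_equal(unname(prs0$raw[, 1]), c(0, 0, 0))
  expect_true(all(is.na(prs0$standardized[, 1])))
})

test_that("standardized scores have mean 0 and unit SD; raw scores scale linearly in beta", {
  geno <- random_panel(n = 80, m = 20, seed = 9)
  set.seed(10)
  st <- toy_stats(20, beta = rnorm(20), p = runif(20),
                  chr = geno$snp_meta$chr, bp = geno$snp_meta$bp)
  prs <- compute_prs(st, geno, p_thresholds = c(0.5, 1))
  expect_equal(mean(prs$standardized[, "1"]), 0, tolerance = 1e-10)
  expect_equal(sd(prs$standardized[, "1"]), 1, tolerance = 1e-10)
  st2 <- st
  st2$beta <- 3 * st$beta
  prs2 <- compute_prs(st2, geno, p_thresholds = c(0.5, 1))
  expect_equal(prs2$raw, 3 * prs$raw, tolerance = 1e-12)
  expect_equal(prs2$standardized, prs$standardized, tolerance = 1e-10)
})

test_that("region exclusion and restriction control the SNP set", {
  geno <- toy_geno(matrix(sample(0:2, 300, TRUE), 100, 3),
                   bp = c(1000L, 2000L, 900000L))
  set.seed(11)
  st <- toy_stats(3, beta = rnorm(3), p = c(0.01, 0.01, 0.01),
                  bp = c(1000L, 2000L, 900000L))
  apoe_like <- genomic_region(1, 500, 3000, "locus")
  prs_ex <- compute_prs(st, geno, p_thresholds = 1, exclude = apoe_like)
  expect_equal(unname(prs_ex$n_snps_used["1"]), 1L)
  prs_in <- compute_prs(st, geno, p_thresholds = 1, restrict_to = apoe_like)
  expect_equal(unname(prs_in$n_snps_used["1"]), 2L)
  expect_warning(compute_prs(st, geno, p_thresholds = 1,
                             exclude = genomic_region(1, 1, 1e9)),
                 "no SNPs")
})

test_that("missing dosages are mean-imputed so every individual uses the full SNP set", {
  dos <- matrix(c(0L, 1L, 2L, NA, 1L, 1L), 3, 2)
  geno <- toy_geno(dos)
  st <- toy_stats(2, beta = c(1, 1), p = c(0.5, 0.5))
  prs <- compute_prs(st, geno, p_thresholds = 1)
  # individual 1: (0 + mean(1,1)) / 2 = 0.5
  expect_equal(unname(prs$raw[1, 1]), 0.5)
})

test_that("denominator flag switches between per-SNP and per-allele averaging", {
  geno <- toy_geno(matrix(c(0L, 1L, 2L), 3, 1))
  st <- toy_stats(1, beta = 1, p = 0.5)
  a <- compute_prs(st, geno, p_thresholds = 1)
  b <- compute_prs(st, geno, p_thresholds = 1, denominator = "alleles")
  expect_equal(unname(b$raw[, 1]), unname(a$raw[, 1]) / 2)
})
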
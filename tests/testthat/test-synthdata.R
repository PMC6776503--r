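test_that("simulation is deterministic under a fixed seed", {
  spec <- simulation_spec(n_individuals = 60, n_snps = 80, n_causal = 10,
                          n_null_endos = 5, seed = 11)
  g1 <- simulate_genotypes(spec)
  g2 <- simulate_genotypes(spec)
  expect_identical(g1$dosages, g2$dosages)
  s1 <- simulate_gwas(g1, spec)
  s2 <- simulate_gwas(g2, spec)
  expect_identical(s1, s2)
  c1 <- simulate_cohort(g1, s1, spec)
  c2 <- simulate_cohort(g2, s2, spec)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$endophenotypes$values, c2$endophenotypes$values)
})

test_that("spec validation names the offending field", {
  expect_error(simulation_spec(rho = 1.2), "rho")
  expect_error(simulation_spec(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(simulation_spec(n_causal = 50, n_snps = 10), "n_causal")
  expect_error(simulation_spec(h2_liability = 1.5), "h2_liability")
  # variance budget: overloaded mediation weights must be rejected
  heavy <- list(e1 = c(0.9, 0.9), e2 = c(0.9, 0.9), e3 = c(0.9, 0.9))
  expect_error(simulation_spec(mediation_weights = heavy, direct_effect = 0.5),
               "variance budget")
})

test_that("rho = 0 gives independent SNPs; allele frequencies stay in range", {
  spec <- simulation_spec(n_individuals = 2000, n_snps = 60, rho = 0,
                          seed = 21)
  g <- simulate_genotypes(spec)
  dos <- g$dosages
  r_adj <- sapply(seq_len(ncol(dos) - 1),
                  function(j) cor(dos[, j], dos[, j + 1]))
  expect_lt(max(r_adj^2), 0.02)
  freq <- colMeans(dos) / 2
  tol <- 3 / sqrt(2 * nrow(dos))
  maf <- attr(g, "maf")
  expect_true(all(abs(freq - maf) < tol))
  expect_true(all(maf >= spec$maf_range[1] & maf <= spec$maf_range[2]))
})

test_that("adjacent-SNP correlation matches the latent-Gaussian tetrachoric value", {
  # at allele frequency ~0.5, the haplotype (and hence dosage) correlation
  # implied by latent rho is (P11 - 1/4) / (1/4) with
  # P11 = 1/4 + asin(rho) / (2*pi)
  rho <- 0.9
  spec <- simulation_spec(n_individuals = 5000, n_snps = 40, rho = rho,
                          block_size = 40, maf_range = c(0.4999, 0.49999),
                          n_causal = 10, seed = 31)
  g <- simulate_genotypes(spec)
  p11 <- 1 / 4 + asin(rho) / (2 * pi)
  expected <- (p11 - 0.25) / 0.25
  r_adj <- sapply(seq_len(39), function(j) cor(g$dosages[, j], g$dosages[, j + 1]))
  expect_lt(abs(mean(r_adj) - expected), 0.05)
})

test_that("LD resets across block boundaries", {
  spec <- simulation_spec(n_individuals = 3000, n_snps = 40, rho = 0.9,
                          block_size = 10, n_causal = 10, seed = 41)
  g <- simulate_genotypes(spec)
  # SNPs 10 and 11 straddle a block boundary
  expect_lt(cor(g$dosages[, 10], g$dosages[, 11])^2, 0.02)
  expect_gt(cor(g$dosages[, 11], g$dosages[, 12])^2, 0.1)
})

test_that("GWAS effects are exact in the noiseless limit and well-calibrated under the null", {
  spec <- simulation_spec(n_individuals = 300, n_snps = 100, n_causal = 20,
                          gwas_n = Inf, seed = 51)
  g <- simulate_genotypes(spec)
  st <- simulate_gwas(g, spec)
  expect_lt(max(abs(st$beta - st$beta_true)), 1e-6)

  spec0 <- simulation_spec(n_individuals = 400, n_snps = 10000, n_causal = 0,
                           rho = 0, seed = 52)
  g0 <- simulate_genotypes(spec0)
  st0 <- simulate_gwas(g0, spec0)
  expect_true(all(st0$beta_true == 0))
  frac <- mean(st0$p < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
})

test_that("strong causal effects keep their sign in the reported statistics", {
  spec <- simulation_spec(n_individuals = 500, n_snps = 2000, n_causal = 2000,
                          h2_liability = 0.9, gwas_n = 1e5, rho = 0, seed = 61)
  g <- simulate_genotypes(spec)
  st <- simulate_gwas(g, spec)
  strong <- abs(st$beta_true) >= 5 * st$se
  expect_gt(sum(strong), 100)
  expect_gte(mean(sign(st$beta[strong]) == sign(st$beta_true[strong])), 0.99)
})

test_that("planted single-mediator chain reproduces its closed-form covariance", {
  spec <- simulation_spec(
    n_individuals = 5000, n_snps = 200, n_causal = 40, seed = 71,
    mediation_weights = list(pathology_e = c(0.5, 0.5)), direct_effect = 0.2,
    covariate_effects = c(age = 0, sex = 0, educ = 0, pc1 = 0, pc2 = 0, pc3 = 0)
  )
  g <- simulate_genotypes(spec)
  st <- simulate_gwas(g, spec)
  co <- simulate_cohort(g, st, spec)
  gl <- co$truth$liability
  e <- co$endophenotypes$values[, "pathology_e"]
  m <- co$truth$motor
  emp <- cov(cbind(gl, e, m))
  a <- 0.5; b <- 0.5; cc <- 0.2
  theo <- matrix(c(1, a, cc + a * b,
                   a, 1, cc * a + b,
                   cc + a * b, cc * a + b, 1), 3, 3)
  expect_lt(max(abs(emp - theo)), 0.05)
})

test_that("no-mediation and full-mediation limits behave", {
  spec0 <- simulation_spec(
    n_individuals = 2000, n_snps = 100, n_causal = 20, seed = 81,
    mediation_weights = list(mirna_x = c(0, 0.4)), direct_effect = 0.5
  )
  g <- simulate_genotypes(spec0)
  st <- simulate_gwas(g, spec0)
  co <- simulate_cohort(g, st, spec0)
  expect_lt(abs(cor(co$endophenotypes$values[, "mirna_x"],
                    co$truth$liability)), 0.05)
  expect_equal(true_mediated_fraction(spec0), 0)

  spec1 <- simulation_spec(mediation_weights = list(protein_y = c(0.5, 0.5)),
                           direct_effect = 0)
  expect_equal(true_mediated_fraction(spec1), 1)
})

test_that("back-generated items carry the outcome signal with stated orientation", {
  spec <- simulation_spec(n_individuals = 1500, n_snps = 100, n_causal = 20,
                          seed = 91)
  g <- simulate_genotypes(spec)
  st <- simulate_gwas(g, spec)
  co <- simulate_cohort(g, st, spec)
  phen <- co$phenotypes
  motor <- co$truth$motor
  expect_lt(cor(phen$grip, motor), -0.5)       # strength: higher = better
  expect_gt(cor(phen$walk_time, motor), 0.5)   # times: higher = worse
  expect_gt(cor(phen$gait_sign, motor), 0.4)   # signs score impairment
  expect_true(all(phen$gait_sign >= 0 & phen$gait_sign <= 100))
  expect_gt(mean(phen$rigidity_sign == 0), 0.05)  # genuine absent signs
})

test_that("missing genotypes are injected at the requested rate", {
  spec <- simulation_spec(n_individuals = 400, n_snps = 200,
                          missing_rate = 0.05, seed = 101)
  g <- simulate_genotypes(spec)
  expect_lt(abs(mean(is.na(g$dosages)) - 0.05), 0.01)
})
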
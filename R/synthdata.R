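# Synthetic cohort generator: blocked-LD genotypes, an external GWAS with a
# known causal subset, covariates, endophenotype layers partially driven by
# genetic liability, and motor outcomes with a planted mediation structure.
# Every downstream stage of the pipeline is testable against the planted
# truth without any access-controlled data.

#' Simulation specification for the synthetic cohort
#'
#' Collects every parameter of the generative model: cohort and panel sizes,
#' LD structure, the genetic architecture of the liability, the external GWAS
#' used for summary statistics, and the planted mediation cascade from
#' genetic liability through endophenotypes to the motor outcome.
#'
#' The outcome model is \code{motor = c*g + sum_j b_j*e_j + covariates + noise}
#' with \code{e_j = a_j*g + noise_j}, all of \code{g} and \code{e_j} on unit
#' variance scale. The residual noise variance is set so that the genetic plus
#' endophenotype portion of the outcome has variance exactly 1; covariate
#' effects add variance on top and are removed again by residualization
#' downstream. The implied true mediated fraction of the genetic effect is
#' \code{sum(a*b) / (c + sum(a*b))}.
#'
#' @param n_individuals cohort size.
#' @param n_snps number of biallelic SNPs on the panel.
#' @param block_size SNPs per LD block; the latent autoregression resets at
#'   block (and chromosome) boundaries.
#' @param rho within-block adjacent-SNP haplotype correlation on the latent
#'   Gaussian scale, in [0, 1).
#' @param maf_range length-2 numeric, bounds for per-SNP minor allele
#'   frequencies, inside (0, 0.5).
#' @param n_causal number of causal SNPs behind the liability.
#' @param h2_liability fraction of liability variance attributable to the
#'   causal SNPs, in [0, 1].
#' @param gwas_n external GWAS sample size controlling summary-statistic
#'   noise; \code{Inf} gives noiseless effect estimates.
#' @param mediation_weights named list mapping endophenotype name to
#'   \code{c(a, b)}: the effect of liability on the endophenotype and of the
#'   endophenotype on the motor outcome. Names carry a category prefix
#'   (\code{pathology_}, \code{methyl_}, \code{acetyl_}, \code{express_},
#'   \code{mirna_}, \code{protein_}).
#' @param direct_effect liability-to-motor effect not passing through any
#'   endophenotype.
#' @param covariate_effects named numeric, linear effects of standardized
#'   covariates (age, sex, educ, pc1..pc3) on the motor outcome.
#' @param n_null_endos number of pure-noise endophenotypes appended to the
#'   matrix (spread over the categories) so screening has a null background.
#' @param missing_rate fraction of genotype calls set missing.
#' @param seed integer master seed; each operation draws from its own named
#'   stream derived from it.
#' @return object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_individuals = 2000,
                            n_snps = 5000,
                            block_size = 20,
                            rho = 0.8,
                            maf_range = c(0.05, 0.45),
                            n_causal = 50,
                            h2_liability = 0.3,
                            gwas_n = 5e4,
                            mediation_weights = default_mediation_weights(),
                            direct_effect = 0.24,
                            covariate_effects = c(age = 0.3, sex = 0.1,
                                                  educ = -0.1, pc1 = 0,
                                                  pc2 = 0, pc3 = 0),
                            n_null_endos = 100,
                            missing_rate = 0,
                            seed = 1L) {
  n_individuals <- check_count(n_individuals, "n_individuals", 2L)
  n_snps <- check_count(n_snps, "n_snps", 1L)
  block_size <- check_count(block_size, "block_size", 1L)
  check_range(rho, "rho", 0, 1, hi_open = TRUE)
  if (!is.numeric(maf_range) || length(maf_range) != 2L) {
    fail_field("maf_range", "must be length-2 numeric (low, high)")
  }
  if (!(0 < maf_range[1] && maf_range[1] <= maf_range[2] && maf_range[2] < 0.5)) {
    fail_field("maf_range", "requires 0 < low <= high < 0.5")
  }
  n_causal <- check_count(n_causal, "n_causal", 0L)
  if (n_causal > n_snps) fail_field("n_causal", "cannot exceed n_snps")
  check_range(h2_liability, "h2_liability", 0, 1)
  if (!(is.numeric(gwas_n) && length(gwas_n) == 1L && gwas_n > 0)) {
    fail_field("gwas_n", "must be a positive number (Inf allowed)")
  }
  if (length(mediation_weights)) {
    if (is.null(names(mediation_weights)) || any(names(mediation_weights) == "")) {
      fail_field("mediation_weights", "must be a named list")
    }
    for (nm in names(mediation_weights)) {
      w <- mediation_weights[[nm]]
      if (!is.numeric(w) || length(w) != 2L || any(is.na(w))) {
        fail_field("mediation_weights", sprintf("entry %s must be c(a, b)", nm))
      }
      if (abs(w[1]) > 1) {
        fail_field("mediation_weights",
                   sprintf("|a| for %s must be <= 1 (endophenotypes are unit variance)", nm))
      }
    }
  }
  check_range(missing_rate, "missing_rate", 0, 1, hi_open = TRUE)
  check_count(n_null_endos, "n_null_endos", 0L)

  spec <- structure(list(
    n_individuals = n_individuals, n_snps = n_snps, block_size = block_size,
    rho = rho, maf_range = maf_range, n_causal = n_causal,
    h2_liability = h2_liability, gwas_n = gwas_n,
    mediation_weights = mediation_weights, direct_effect = direct_effect,
    covariate_effects = covariate_effects, n_null_endos = n_null_endos,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "simulation_spec")

  # variance budget: the structural (non-covariate) part of the outcome must
  # fit inside unit variance before residual noise is added
  if (structural_variance(spec) > 1 + 1e-12) {
    fail_field("mediation_weights",
               sprintf("inconsistent variance budget: structural outcome variance %.3f > 1",
                       structural_variance(spec)))
  }
  spec
}

#' @rdname simulation_spec
#' @export
default_mediation_weights <- function() {
  list(
    pathology_tangle   = c(0.30, 0.20),
    pathology_arterio  = c(0.30, 0.20),
    acetyl_m1          = c(0.30, 0.20),
    express_m1         = c(0.30, 0.20),
    mirna_1            = c(0.30, 0.20),
    protein_1          = c(0.30, 0.20)
  )
}

# variance of c*g + sum b_j e_j with e_j = a_j g + sqrt(1-a_j^2) noise:
# (c + sum a_j b_j)^2 + sum b_j^2 (1 - a_j^2)
structural_variance <- function(spec) {
  if (!length(spec$mediation_weights)) return(spec$direct_effect^2)
  a <- vapply(spec$mediation_weights, `[`, numeric(1), 1L)
  b <- vapply(spec$mediation_weights, `[`, numeric(1), 2L)
  (spec$direct_effect + sum(a * b))^2 + sum(b^2 * (1 - a^2))
}

#' True mediated fraction implied by a simulation spec
#'
#' \code{sum(a*b) / (c + sum(a*b))}: the share of the total liability-to-motor
#' effect that passes through the planted endophenotypes.
#' @param spec a \code{simulation_spec}.
#' @return numeric in [0, 1] (NA when the total effect is zero).
#' @export
true_mediated_fraction <- function(spec) {
  a <- vapply(spec$mediation_weights, `[`, numeric(1), 1L)
  b <- vapply(spec$mediation_weights, `[`, numeric(1), 2L)
  tot <- spec$direct_effect + sum(a * b)
  if (tot == 0) return(NA_real_)
  sum(a * b) / tot
}

#' Construct a genotype matrix object
#'
#' @param dosages individuals x SNPs integer matrix with values 0/1/2 or NA.
#' @param snp_meta data.frame with columns snp, chr, bp, a1 (counted allele),
#'   a2; positions must be strictly increasing within chromosome.
#' @param sample_ids character vector of row identifiers.
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosages, snp_meta, sample_ids) {
  stopifnot(is.matrix(dosages), nrow(snp_meta) == ncol(dosages),
            length(sample_ids) == nrow(dosages))
  need <- c("snp", "chr", "bp", "a1", "a2")
  if (!all(need %in% names(snp_meta))) {
    stop("snp_meta needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(snp_meta$snp)) stop("snp ids must be unique", call. = FALSE)
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  for (ch in unique(snp_meta$chr)) {
    bp <- snp_meta$bp[snp_meta$chr == ch]
    if (any(diff(bp) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
    }
  }
  dimnames(dosages) <- list(sample_ids, snp_meta$snp)
  structure(list(dosages = dosages, snp_meta = snp_meta,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$snp_meta$chr))))
  cat(sprintf("  missing calls: %.3f%%\n", 100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Simulate blocked-LD genotypes
#'
#' Haplotypes are drawn from a blocked first-order autoregressive latent
#' Gaussian (correlation \code{rho} between adjacent SNPs within a block,
#' zero across block and chromosome boundaries) and thresholded at the
#' per-SNP allele-frequency quantile; the dosage is the sum of two
#' independent haplotypes. Deterministic given \code{spec$seed}.
#'
#' @param spec a \code{simulation_spec}.
#' @return a \code{genotype_matrix} with per-SNP metadata (chromosome,
#'   position, alleles) and, as attribute \code{"maf"}, the generating allele
#'   frequencies.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_individuals
  m <- spec$n_snps

  # panel layout: ~500 SNPs per chromosome at 5 kb spacing, blocks inside
  snps_per_chrom <- 500L
  chr <- 1L + (seq_len(m) - 1L) %/% snps_per_chrom
  idx_in_chrom <- 1L + (seq_len(m) - 1L) %% snps_per_chrom
  bp <- idx_in_chrom * 5000L
  block <- (seq_len(m) - 1L) %/% spec$block_size
  new_block <- c(TRUE, diff(block) != 0 | diff(chr) != 0)

  with_stream(spec$seed, "genotypes", {
    maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
    thr <- qnorm(1 - maf)           # latent > thr  <=>  carry counted allele
    rho <- spec$rho
    z <- matrix(rnorm(2L * n * m), nrow = 2L * n, ncol = m)
    if (rho > 0) {
      w <- sqrt(1 - rho^2)
      for (j in seq_len(m)[-1L]) {
        if (!new_block[j]) z[, j] <- rho * z[, j - 1L] + w * z[, j]
      }
    }
    hap <- z > rep(thr, each = 2L * n)
    dos <- hap[seq_len(n), , drop = FALSE] +
      hap[n + seq_len(n), , drop = FALSE]
    storage.mode(dos) <- "integer"
    if (spec$missing_rate > 0) {
      dos[runif(length(dos)) < spec$missing_rate] <- NA_integer_
    }
    alleles <- sample_allele_pairs(m)
    meta <- data.frame(
      snp = sprintf("snp%05d", seq_len(m)), chr = chr, bp = bp,
      a1 = alleles$a1, a2 = alleles$a2, stringsAsFactors = FALSE
    )
    g <- genotype_matrix(dos, meta, sprintf("id%04d", seq_len(n)))
    attr(g, "maf") <- maf
    g
  })
}

# mostly non-ambiguous allele pairs; a small fraction strand-ambiguous
# (A/T, C/G) so harmonization's ambiguity filter is exercised
sample_allele_pairs <- function(m, frac_ambiguous = 0.02) {
  nonamb <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                 c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
  amb <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  pick <- ifelse(runif(m) < frac_ambiguous,
                 sample.int(4L, m, replace = TRUE) + 8L,
                 sample.int(8L, m, replace = TRUE))
  pool <- c(nonamb, amb)
  a1 <- vapply(pick, function(i) pool[[i]][1], character(1))
  a2 <- vapply(pick, function(i) pool[[i]][2], character(1))
  list(a1 = a1, a2 = a2)
}

#' Simulate external GWAS summary statistics with a known causal subset
#'
#' Draws true per-allele effects for a random causal subset, scaled so that
#' the causal SNPs explain \code{h2_liability} of the liability variance, and
#' reports noisy estimates \code{beta = beta_true + e} with
#' \code{SE = 1/sqrt(gwas_n * 2*maf*(1-maf))} and Wald p-values, emulating an
#' external case-control GWAS of size \code{gwas_n}.
#'
#' @param geno a \code{genotype_matrix} from \code{\link{simulate_genotypes}}.
#' @param spec the matching \code{simulation_spec}.
#' @return a \code{summary_stats} data.frame (snp, chr, bp, a1, a2, beta, se,
#'   p) with an extra hidden-truth column \code{beta_true} (dropped by the
#'   TSV writer).
#' @export
simulate_gwas <- function(geno, spec) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(spec, "simulation_spec"))
  if (spec$n_causal > nrow(geno$snp_meta)) {
    fail_field("n_causal", "exceeds number of SNPs in the panel")
  }
  freq <- colMeans(geno$dosages, na.rm = TRUE) / 2
  degenerate <- freq <= 0 | freq >= 1 | is.na(freq)
  if (any(degenerate)) {
    warning(sprintf("%d SNP(s) with degenerate allele frequency skipped",
                    sum(degenerate)))
  }
  with_stream(spec$seed, "gwas", {
    m <- nrow(geno$snp_meta)
    beta_true <- numeric(m)
    eligible <- which(!degenerate)
    causal <- if (spec$n_causal > 0) {
      sample(eligible, min(spec$n_causal, length(eligible)))
    } else integer(0)
    if (length(causal)) {
      u <- rnorm(length(causal))
      # scale so sum beta^2 * 2p(1-p) = h2_liability
      v <- sum(u^2 * 2 * freq[causal] * (1 - freq[causal]))
      beta_true[causal] <- if (v > 0) u * sqrt(spec$h2_liability / v) else 0
    }
    se <- 1 / sqrt(spec$gwas_n * 2 * freq * (1 - freq))
    se[degenerate] <- NA_real_
    beta <- beta_true + ifelse(is.finite(se), rnorm(m) * se, 0)
    beta[!is.finite(se)] <- beta_true[!is.finite(se)]  # gwas_n = Inf: se == 0
    se[is.infinite(spec$gwas_n) | se == 0] <- 0
    z <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
    p <- pmax(2 * pnorm(-abs(z)), 1e-300)
    out <- data.frame(
      snp = geno$snp_meta$snp, chr = geno$snp_meta$chr, bp = geno$snp_meta$bp,
      a1 = geno$snp_meta$a1, a2 = geno$snp_meta$a2,
      beta = beta, se = se, p = p, beta_true = beta_true,
      stringsAsFactors = FALSE
    )
    out <- out[!degenerate, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("summary_stats", "data.frame")
    out
  })
}

#' Simulate the cohort phenotypes with a planted mediation cascade
#'
#' Builds the genetic liability \code{g} from the true causal effects,
#' generates covariates (age, sex, education, three ancestry PCs),
#' endophenotype layers \code{e_j = a_j*g + noise}, and the motor outcome
#' \code{motor = c*g + sum_j b_j*e_j + covariate effects + noise}. Raw motor
#' test items (ten performance measures and four parkinsonian signs) are
#' back-generated from the outcome so composite scoring can be exercised.
#'
#' @param geno a \code{genotype_matrix}.
#' @param truth \code{summary_stats} carrying the hidden \code{beta_true}
#'   column (as returned by \code{\link{simulate_gwas}}).
#' @param spec the matching \code{simulation_spec}.
#' @return list with \code{phenotypes} (data.frame: sample_id, covariates,
#'   diagnoses, raw motor items), \code{endophenotypes} (an
#'   \code{endophenotype_matrix}), and \code{truth} (a \code{truth_record}
#'   with the planted coefficients, the liability and latent outcome, and the
#'   implied true mediated fraction).
#' @export
simulate_cohort <- function(geno, truth, spec) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(spec, "simulation_spec"))
  if (!"beta_true" %in% names(truth)) {
    stop("`truth` must carry the simulation's beta_true column", call. = FALSE)
  }
  if (structural_variance(spec) > 1 + 1e-12) {
    fail_field("mediation_weights", "inconsistent variance budget")
  }
  n <- nrow(geno$dosages)
  dos <- impute_mean_dosage(geno$dosages)
  keep <- match(truth$snp, colnames(dos))
  g_raw <- as.vector(dos[, keep[!is.na(keep)], drop = FALSE] %*%
                       truth$beta_true[!is.na(keep)])
  g <- if (sd(g_raw) > 0) (g_raw - mean(g_raw)) / sd(g_raw) else g_raw

  with_stream(spec$seed, "cohort", {
    cov_tab <- data.frame(
      age = rnorm(n, 80, 7), sex = rbinom(n, 1, 0.5),
      educ = rnorm(n, 16, 3), pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n)
    )

    mw <- spec$mediation_weights
    a <- vapply(mw, `[`, numeric(1), 1L)
    b <- vapply(mw, `[`, numeric(1), 2L)
    k <- length(mw)
    endo <- matrix(NA_real_, n, k + spec$n_null_endos)
    nm <- character(k + spec$n_null_endos)
    for (j in seq_len(k)) {
      endo[, j] <- a[j] * g + sqrt(1 - a[j]^2) * rnorm(n)
      nm[j] <- names(mw)[j]
    }
    cats <- c("pathology", "methyl", "acetyl", "express", "mirna", "protein")
    for (j in seq_len(spec$n_null_endos)) {
      endo[, k + j] <- rnorm(n)
      nm[k + j] <- sprintf("%s_null%03d", cats[1L + (j - 1L) %% 6L], j)
    }
    colnames(endo) <- nm

    struct <- spec$direct_effect * g +
      (if (k > 0) as.vector(endo[, seq_len(k), drop = FALSE] %*% b) else 0)
    noise_var <- max(0, 1 - structural_variance(spec))
    motor_latent <- struct + rnorm(n, sd = sqrt(noise_var))

    ce <- spec$covariate_effects
    cov_std <- scale(as.matrix(cov_tab[, names(ce), drop = FALSE]))
    motor <- motor_latent + as.vector(cov_std %*% ce)

    # clinical diagnoses: AD driven by liability and age, PD mostly noise
    ad <- rbinom(n, 1, stats::plogis(-1.2 + 0.8 * g + 0.4 * zscale(cov_tab$age)))
    pd <- rbinom(n, 1, stats::plogis(-3 + 0.15 * g))

    items <- back_generate_items(motor)
    phen <- cbind(data.frame(sample_id = geno$sample_ids,
                             stringsAsFactors = FALSE),
                  cov_tab, data.frame(ad_dx = ad, pd_dx = pd), items)

    meta <- data.frame(
      variable = nm,
      category = vapply(strsplit(nm, "_"), `[`, character(1), 1L),
      stringsAsFactors = FALSE
    )
    meta$category <- c(pathology = "pathology", methyl = "methylation-module",
                       acetyl = "acetylation-module",
                       express = "expression-module", mirna = "miRNA",
                       protein = "protein")[meta$category]
    rownames(endo) <- geno$sample_ids
    endos <- endophenotype_matrix(endo, meta)

    tr <- structure(list(
      a = a, b = b, direct = spec$direct_effect,
      causal_snps = truth$snp[truth$beta_true != 0],
      mediated_fraction = true_mediated_fraction(spec),
      liability = g, motor_latent = motor_latent, motor = motor
    ), class = "truth_record")

    list(phenotypes = phen, endophenotypes = endos, truth = tr)
  })
}

# raw test items regenerated from the latent motor impairment score: higher
# latent = worse. Performance items carry item-level noise; signs are 0-100
# with genuine zeros so dichotomization has both classes.
back_generate_items <- function(motor) {
  n <- length(motor)
  perf <- function(mu, sc, worse_is_high) {
    dir <- if (worse_is_high) 1 else -1
    pmax(mu + sc * (dir * motor + rnorm(n, sd = 0.5)), mu * 0.05)
  }
  sign_item <- function(shift) {
    s <- 100 * stats::plogis(0.9 * (motor + rnorm(n, sd = 0.6)) - shift)
    ifelse(s < 12, 0, round(pmin(s, 100), 1))
  }
  data.frame(
    grip = perf(28, 4, FALSE), pinch = perf(6, 1, FALSE),
    pegboard = perf(11, 1.5, FALSE), tapping = perf(50, 6, FALSE),
    walk_time = perf(8, 1.5, TRUE), walk_steps = perf(9, 1.2, TRUE),
    turn_time = perf(4, 0.8, TRUE), turn_steps = perf(7, 1.0, TRUE),
    leg_stand = perf(7, 1.8, FALSE), toe_stand = perf(8, 1.6, FALSE),
    gait_sign = sign_item(1.0), bradykinesia_sign = sign_item(1.2),
    rigidity_sign = sign_item(1.4), tremor_sign = sign_item(1.8)
  )
}

impute_mean_dosage <- function(dos) {
  if (!anyNA(dos)) return(dos)
  mu <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  dos[idx] <- mu[idx[, 2L]]
  dos
}

#' @export
print.truth_record <- function(x, ...) {
  cat("truth_record (planted generative coefficients)\n")
  cat(sprintf("  mediators: %d, direct effect c = %.3f\n", length(x$a), x$direct))
  cat(sprintf("  true mediated fraction: %.3f\n", x$mediated_fraction))
  invisible(x)
}
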
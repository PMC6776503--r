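rand_covs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = rnorm(n, 80, 7), sex = rbinom(n, 1, 0.5),
             educ = rnorm(n, 16, 3), pc1 = rnorm(n), pc2 = rnorm(n),
             pc3 = rnorm(n))
}

test_that("residualization: orthogonal outcome is centered, exact fit is zeroed", {
  covs <- rand_covs(50, 1)
  X <- scale(as.matrix(covs), scale = FALSE)
  y_orth <- rnorm(50)
  y_orth <- y_orth - X %*% solve(crossprod(X), crossprod(X, y_orth))
  r <- residualize(as.vector(y_orth), covs)
  expect_equal(r, as.vector(y_orth - mean(y_orth)), tolerance = 1e-10)

  y_fit <- 2 + 0.3 * covs$age - covs$educ + covs$pc2
  expect_equal(residualize(y_fit, covs), rep(0, 50), tolerance = 1e-10)
})

test_that("residualization matches the normal-equations oracle on a 6-point design", {
  covs <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = c(2, 1, 4, 3, 6, 5))
  y <- c(3, 1, 4, 1, 5, 9)
  X <- cbind(1, as.matrix(covs))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize(y, covs), as.vector(y - X %*% beta),
               tolerance = 1e-12)
})

test_that("collinear covariates are reported", {
  covs <- rand_covs(30, 2)
  covs$dup <- covs$age * 2
  expect_error(residualize(rnorm(30), covs), "dup")
})

test_that("offset logistic with no covariates equals plain logistic regression", {
  set.seed(3)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  got <- offset_logistic_test(y, x)
  ref <- summary(glm(y ~ x, family = binomial()))$coefficients
  expect_equal(got$estimate, ref["x", "Estimate"], tolerance = 1e-8)
  expect_equal(got$p, ref["x", "Pr(>|z|)"], tolerance = 1e-8)
})

test_that("offset logistic approaches the joint fit for covariate-orthogonal predictors", {
  set.seed(4)
  n <- 4000
  covs <- rand_covs(n, 5)
  x <- rnorm(n)  # independent of covariates
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * x + 0.05 * (covs$age - 80)))
  got <- offset_logistic_test(y, x, covs)
  joint <- summary(glm(y ~ ., data = data.frame(y = y, x = x, covs),
                       family = binomial()))$coefficients
  expect_lt(abs(got$estimate - joint["x", "Estimate"]),
            2 * joint["x", "Std. Error"])
})

test_that("offset logistic keeps its nominal type-I error", {
  set.seed(6)
  n <- 800
  reps <- 400
  rej <- logical(reps)
  covs <- rand_covs(n, 7)
  eta <- plogis(-0.4 + 0.05 * (covs$age - 80))
  for (r in seq_len(reps)) {
    y <- rbinom(n, 1, eta)
    x <- rnorm(n)
    rej[r] <- offset_logistic_test(y, x, covs)$p < 0.05
  }
  # 3-sigma Monte Carlo band around 0.05 at 400 replicates
  expect_gt(mean(rej), 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("degenerate outcomes are refused", {
  expect_error(offset_logistic_test(rep(1, 20), rnorm(20)), "classes")
})

test_that("Frisch-Waugh-Lovell: residualized scan equals joint fit for orthogonalized predictors", {
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 150
    covs <- rand_covs(n, 200 + s)
    x <- rnorm(n)
    X <- cbind(1, as.matrix(covs))
    x_orth <- as.vector(x - X %*% solve(crossprod(X), crossprod(X, x)))
    y <- 0.4 * x_orth + 0.2 * covs$pc1 + rnorm(n)
    ry <- residualize(y, covs)
    fit_sep <- lm(ry ~ x_orth)
    fit_joint <- lm(y ~ x_orth + ., data = data.frame(y = y, covs))
    expect_equal(unname(coef(fit_sep)["x_orth"]),
                 unname(coef(fit_joint)["x_orth"]), tolerance = 1e-8)
  }
})

test_that("Bonferroni thresholds reproduce the conventional rounded values", {
  t560 <- bonferroni_threshold(0.05, 560)
  expect_equal(attr(t560, "display"), 8.9e-5)
  expect_equal(as.numeric(t560), 0.05 / 560)
  t13 <- bonferroni_threshold(0.05, 13)
  expect_equal(attr(t13, "display"), 0.0038)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

make_screen_fixture <- function(n = 400, n_null = 50, a = 0.6, b = 0.6,
                                seed = 1) {
  set.seed(seed)
  g <- rnorm(n)
  covs <- rand_covs(n, seed + 1)
  e <- a * g + sqrt(1 - a^2) * rnorm(n)
  y <- b * e + sqrt(1 - b^2 * 1) * rnorm(n)
  vals <- cbind(pathology_hit = e,
                matrix(rnorm(n * n_null), n,
                       dimnames = list(NULL, sprintf("mirna_null%02d", 1:n_null))))
  rownames(vals) <- sprintf("i%03d", 1:n)
  endos <- endophenotype_matrix(
    vals, data.frame(variable = colnames(vals),
                     category = c("pathology", rep("miRNA", n_null))))
  list(endos = endos, outcomes = data.frame(parkinsonism = y), prs = g,
       covs = covs)
}

test_that("the two-stage screen recovers a planted mediator and reports thresholds", {
  fx <- make_screen_fixture(seed = 11)
  sr <- suppressMessages(screen_endophenotypes(fx$endos, fx$outcomes, fx$prs,
                                               fx$covs))
  expect_s3_class(sr, "screen_result")
  expect_true("pathology_hit" %in% sr$stage1_hits)
  expect_true("pathology_hit" %in% sr$stage2_hits)
  expect_equal(sr$thresholds$m1, 51)
  expect_equal(sr$thresholds$thr1, 0.05 / 51)
  expect_equal(sr$thresholds$m2, length(sr$stage1_hits))
  expect_true(all(sr$stage2_hits %in% sr$stage1_hits))
})

test_that("a variable duplicating the outcome is always a stage-1 hit", {
  fx <- make_screen_fixture(seed = 12)
  vals <- fx$endos$values
  vals[, 2] <- fx$outcomes$parkinsonism
  colnames(vals)[2] <- "mirna_copy"
  meta <- fx$endos$meta
  meta$variable[2] <- "mirna_copy"
  endos <- endophenotype_matrix(vals, meta)
  sr <- suppressMessages(suppressWarnings(
    screen_endophenotypes(endos, fx$outcomes, fx$prs, fx$covs)))
  expect_true("mirna_copy" %in% sr$stage1_hits)
})

test_that("all-null screens come back empty with a warning, not an error", {
  set.seed(13)
  n <- 200
  vals <- matrix(rnorm(n * 40), n,
                 dimnames = list(NULL, sprintf("protein_n%02d", 1:40)))
  endos <- endophenotype_matrix(
    vals, data.frame(variable = colnames(vals), category = "protein"))
  covs <- rand_covs(n, 14)
  expect_warning(
    sr <- suppressMessages(screen_endophenotypes(
      endos, data.frame(y = rnorm(n)), rnorm(n), covs)),
    "no stage-1 hits")
  expect_length(sr$stage2_hits, 0)
})

test_that("PRS scan covers thresholds and outcome types with signed p-values", {
  set.seed(15)
  n <- 500
  covs <- rand_covs(n, 16)
  g <- rnorm(n)
  raw <- cbind(`0.05` = g + rnorm(n, sd = 2), `0.5` = g)
  std <- scale(raw)
  prs <- structure(list(raw = raw, standardized = std,
                        thresholds = c(0.05, 0.5),
                        n_snps_used = c(`0.05` = 10L, `0.5` = 100L),
                        excluded = NULL, restricted_to = NULL,
                        denominator = "snps",
                        sample_ids = sprintf("i%03d", 1:n)),
                   class = "prs_result")
  phen <- data.frame(motor = 0.3 * g + rnorm(n),
                     dx = rbinom(n, 1, plogis(-0.5 + 0.5 * g)))
  res <- prs_scan(prs, phen, covs)
  expect_equal(nrow(res), 4)
  expect_true(all(sign(res$signed_log10p) == sign(res$estimate)))
  strong <- res[res$threshold == 0.5 & res$outcome == "motor", ]
  expect_true(strong$significant)
  expect_gt(strong$estimate, 0)
})
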
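# Covariate handling and association scans: residualization of continuous
# outcomes, offset-term logistic models for categorical outcomes, PRS scans
# across inclusion thresholds, and the two-stage Bonferroni endophenotype
# screen.

DEFAULT_COVARIATES <- c("age", "sex", "educ", "pc1", "pc2", "pc3")

#' Residualize a continuous outcome on covariates
#'
#' Ordinary least squares with intercept; the residuals (mean zero by
#' construction) replace the outcome in downstream association tests, so the
#' covariates are removed once rather than refit per scan.
#'
#' @param outcome numeric vector.
#' @param covariates data.frame of covariates (conventionally age, sex,
#'   education and the first three genotyping principal components).
#' @return numeric residual vector (NA where outcome or covariates are
#'   missing).
#' @export
residualize <- function(outcome, covariates) {
  stopifnot(is.numeric(outcome), nrow(covariates) == length(outcome))
  df <- data.frame(.y = outcome, covariates)
  if (sum(complete.cases(df)) <= ncol(covariates) + 1) {
    stop("need n > number of covariates + 1 complete cases", call. = FALSE)
  }
  fit <- lm(.y ~ ., data = df, na.action = stats::na.exclude)
  if (anyNA(coef(fit))) {
    stop("rank-deficient covariate design; collinear columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  as.vector(resid(fit))
}

assoc_row <- function(predictor, outcome, n, est, se, p) {
  p <- min(max(p, 1e-300), 1)
  data.frame(predictor = predictor, outcome = outcome, n = n,
             estimate = est, se = se, p = p,
             signed_log10p = -log10(p) * ifelse(est < 0, -1, 1),
             stringsAsFactors = FALSE)
}

#' Logistic association with covariate offset terms
#'
#' Two-step generalized linear model: (1) the binary outcome is fit on the
#' covariates alone; (2) the outcome is fit on the predictor with the step-1
#' linear predictor entering as a fixed offset, so the covariate
#' coefficients are held constant across all predictors tested against that
#' outcome. The predictor coefficient is reported as a log-odds with a Wald
#' test.
#'
#' @param outcome binary 0/1 vector; both classes must be present.
#' @param predictor numeric vector.
#' @param covariates optional data.frame; with none, the test reduces to an
#'   ordinary single-predictor logistic regression with intercept.
#' @param predictor_id,outcome_id labels carried into the result row.
#' @return one-row association data.frame (estimate, se, p, signed -log10 p).
#' @export
offset_logistic_test <- function(outcome, predictor, covariates = NULL,
                                 predictor_id = "predictor",
                                 outcome_id = "outcome") {
  ok <- !is.na(outcome) & !is.na(predictor)
  if (!is.null(covariates)) ok <- ok & complete.cases(covariates)
  y <- outcome[ok]
  x <- predictor[ok]
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  off <- if (is.null(covariates) || ncol(covariates) == 0) {
    rep(0, length(y))
  } else {
    cv <- covariates[ok, , drop = FALSE]
    base <- glm(y ~ ., data = data.frame(y = y, cv), family = binomial())
    as.vector(predict(base, type = "link"))
  }
  fit <- glm(y ~ x, offset = off, family = binomial())
  co <- summary(fit)$coefficients
  if (!fit$converged || abs(co["x", "Estimate"]) > 15) {
    stop("separation detected for predictor '", predictor_id,
         "'; penalized logistic regression is out of scope here",
         call. = FALSE)
  }
  assoc_row(predictor_id, outcome_id, length(y), co["x", "Estimate"],
            co["x", "Std. Error"], co["x", "Pr(>|z|)"])
}

# slope test of residualized outcome on a predictor (OLS with intercept);
# algebraically the correlation t-test, vectorized over predictor columns
ols_scan <- function(y, X) {
  X <- as.matrix(X)
  m <- ncol(X)
  n <- numeric(m); r <- numeric(m); sdx <- numeric(m); sdy <- numeric(m)
  ok_y <- !is.na(y)
  clean <- !anyNA(X)
  if (clean && all(ok_y)) {
    r <- suppressWarnings(as.vector(cor(y, X)))
    n[] <- length(y)
    sdx <- apply(X, 2, sd)
    sdy[] <- sd(y)
  } else {
    for (j in seq_len(m)) {
      ok <- ok_y & !is.na(X[, j])
      n[j] <- sum(ok)
      r[j] <- suppressWarnings(cor(y[ok], X[ok, j]))
      sdx[j] <- sd(X[ok, j])
      sdy[j] <- sd(y[ok])
    }
  }
  bad <- is.na(r) | n < 4
  r <- pmax(pmin(r, 1), -1)
  est <- r * sdy / sdx
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- pmin(pmax(2 * pt(-abs(tstat), n - 2), 1e-300), 1)
  se <- sdy * sqrt(pmax(1 - r^2, 0)) / (sdx * sqrt(pmax(n - 2, 1)))
  est[bad] <- NA_real_; se[bad] <- NA_real_; p[bad] <- 1
  data.frame(predictor = colnames(X), outcome = "outcome", n = n,
             estimate = est, se = se, p = p,
             signed_log10p = -log10(p) * ifelse(!is.na(est) & est < 0, -1, 1),
             stringsAsFactors = FALSE)
}

#' Scan PRS thresholds against phenotypes
#'
#' For every (inclusion threshold, outcome) pair: continuous outcomes are
#' residualized on the covariates and regressed on the standardized PRS;
#' binary outcomes (clinical diagnoses) are tested with
#' \code{\link{offset_logistic_test}}. Rows are flagged significant at the
#' conventional scan threshold p < 0.001.
#'
#' @param prs a \code{prs_result}.
#' @param phenotypes data.frame of outcomes (columns with only 0/1 values are
#'   treated as binary).
#' @param covariates data.frame of covariates.
#' @param alpha scan significance threshold (default 0.001).
#' @return data.frame with one row per threshold x outcome, columns
#'   threshold, outcome, n, estimate, se, p, signed_log10p, significant.
#' @export
prs_scan <- function(prs, phenotypes, covariates, alpha = 0.001) {
  stopifnot(inherits(prs, "prs_result"))
  rows <- list()
  for (oc in names(phenotypes)) {
    y <- phenotypes[[oc]]
    vals <- unique(y[!is.na(y)])
    binary <- length(vals) <= 2 && all(vals %in% c(0, 1))
    ry <- if (binary) NULL else residualize(y, covariates)
    for (t in prs$thresholds) {
      x <- prs_vector(prs, t)
      if (all(is.na(x))) next
      row <- if (binary) {
        offset_logistic_test(y, x, covariates, predictor_id = "prs",
                             outcome_id = oc)
      } else {
        r <- ols_scan(ry, matrix(x, dimnames = list(NULL, "prs")))
        r$outcome <- oc
        r
      }
      row$threshold <- t
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("threshold", "outcome", "n", "estimate", "se", "p",
                 "signed_log10p")]
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return exact threshold \code{alpha/m}; the conventional two-significant-
#'   figure display value is attached as attribute \code{"display"}.
#' @export
bonferroni_threshold <- function(alpha, m) {
  check_range(alpha, "alpha", 0, 1, lo_open = TRUE, hi_open = TRUE)
  m <- check_count(m, "m", 1L)
  thr <- alpha / m
  attr(thr, "display") <- signif(thr, 2)
  thr
}

#' Two-stage endophenotype screen
#'
#' Stage 1: every endophenotype is tested against every named motor outcome
#' (outcomes residualized on the covariates, OLS slope test); variables with
#' p below the Bonferroni threshold \code{alpha / m1} for at least one
#' outcome are kept (m1 = number of variables). Stage 2: the kept variables
#' are residualized on the covariates and tested against the PRS; hits are
#' those with p below \code{alpha / m2} (m2 = realized stage-1 hit count).
#'
#' @param endos an \code{endophenotype_matrix}.
#' @param outcomes data.frame of motor outcomes (continuous).
#' @param prs a \code{prs_result} or a numeric PRS vector.
#' @param covariates data.frame of covariates.
#' @param alpha family-wise error rate per stage (default 0.05).
#' @return object of class \code{screen_result}: stage-1 and stage-2 result
#'   tables, hit lists, and the thresholds used.
#' @export
screen_endophenotypes <- function(endos, outcomes, prs, covariates,
                                  alpha = 0.05) {
  stopifnot(inherits(endos, "endophenotype_matrix"))
  prs_v <- if (inherits(prs, "prs_result")) prs_vector(prs) else prs
  m1 <- ncol(endos$values)
  thr1 <- bonferroni_threshold(alpha, m1)

  s1 <- list()
  for (oc in names(outcomes)) {
    ry <- residualize(outcomes[[oc]], covariates)
    tab <- ols_scan(ry, endos$values)
    tab$outcome <- oc
    s1[[oc]] <- tab
  }
  stage1 <- do.call(rbind, s1)
  names(stage1)[names(stage1) == "predictor"] <- "variable"
  rownames(stage1) <- NULL
  hits1 <- sort(unique(stage1$variable[stage1$p < thr1]))

  m2 <- length(hits1)
  thr2 <- if (m2 > 0) bonferroni_threshold(alpha, m2) else NA_real_
  stage2 <- NULL
  hits2 <- character(0)
  if (m2 == 0) {
    warning("no stage-1 hits; stage 2 skipped")
  } else {
    rows <- list()
    for (v in hits1) {
      rv <- residualize(endos$values[, v], covariates)
      row <- ols_scan(rv, matrix(prs_v, dimnames = list(NULL, "prs")))
      row$predictor <- "prs"
      row$outcome <- v
      rows[[v]] <- row
    }
    stage2 <- do.call(rbind, rows)
    names(stage2)[names(stage2) == "outcome"] <- "variable"
    rownames(stage2) <- NULL
    hits2 <- sort(stage2$variable[stage2$p < thr2])
  }
  log_msg("assoc", "screen: m1=%d (p<%.3g) -> %d hits; m2=%d (p<%.3g) -> %d hits",
          m1, thr1, length(hits1), m2,
          if (is.na(thr2)) NA else thr2, length(hits2))
  structure(list(stage1 = stage1, stage1_hits = hits1, stage2 = stage2,
                 stage2_hits = hits2,
                 thresholds = list(alpha = alpha, m1 = m1, thr1 = as.numeric(thr1),
                                   m2 = m2, thr2 = as.numeric(thr2))),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  t <- x$thresholds
  cat(sprintf("screen_result: stage 1 %d variables (p < %.3g) -> %d hits\n",
              t$m1, t$thr1, length(x$stage1_hits)))
  cat(sprintf("               stage 2 %d variables (p < %.3g) -> %d hits\n",
              t$m2, if (is.na(t$thr2)) NaN else t$thr2, length(x$stage2_hits)))
  if (length(x$stage2_hits)) {
    cat("  mediator candidates: ", paste(x$stage2_hits, collapse = ", "), "\n")
  }
  invisible(x)
}
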
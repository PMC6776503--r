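# Variance-explained mediation decomposition: how much of the PRS-to-motor
# effect each endophenotype accounts for, via exact LMG relative-importance
# shares of R^2.

# R^2 of y on every subset of predictors, from the joint covariance matrix;
# subsets indexed by bitmask. Exact, O(2^p) small-matrix solves.
all_subset_r2 <- function(y, X) {
  X <- as.matrix(X)
  ok <- !is.na(y) & complete.cases(X)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  p <- ncol(X)
  if (p > 12) {
    stop("more than 12 predictors: exact ordering enumeration is infeasible; ",
         "reduce the predictor set (sampling approximations are out of scope)",
         call. = FALSE)
  }
  if (sd(y) == 0 || any(apply(X, 2, sd) == 0)) {
    stop("zero-variance input", call. = FALSE)
  }
  S <- cov(cbind(y, X))
  syy <- S[1, 1]
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    Sxx <- S[idx + 1L, idx + 1L, drop = FALSE]
    sxy <- S[idx + 1L, 1L]
    # pseudoinverse: exactly collinear predictor subsets (e.g. duplicated
    # variables) still have a well-defined R^2
    r2[mask + 1L] <- as.numeric(crossprod(sxy, MASS::ginv(Sxx) %*% sxy)) / syy
  }
  list(r2 = r2, p = p, n = length(y))
}

#' Exact LMG relative-importance decomposition
#'
#' The LMG share of a predictor is its sequential increase in R^2 averaged
#' over all orderings in which the predictors can enter the model, computed
#' exactly by enumerating predictor subsets with combinatorial weights.
#' Shares always sum to the full model's R^2.
#'
#' @param outcome numeric vector.
#' @param predictors data.frame or matrix of at most 12 predictors.
#' @return named numeric vector of shares, with the full-model R^2 as
#'   attribute \code{"r2_total"} and the complete-case n as \code{"n"}.
#' @export
lmg_decompose <- function(outcome, predictors) {
  sub <- all_subset_r2(outcome, predictors)
  p <- sub$p
  r2 <- sub$r2
  wts <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - 0:(p - 1)) -
               lfactorial(p))
  shares <- numeric(p)
  bits <- bitwShiftL(1L, seq_len(p) - 1L)
  masks <- 0:(2^p - 1L)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bits) != 0L), integer(1))
  for (k in seq_len(p)) {
    without <- masks[bitwAnd(masks, bits[k]) == 0L]
    gain <- r2[without + bits[k] + 1L] - r2[without + 1L]
    shares[k] <- sum(wts[sizes[without + 1L] + 1L] * gain)
  }
  names(shares) <- colnames(as.matrix(predictors))
  attr(shares, "r2_total") <- r2[2^p]
  attr(shares, "n") <- sub$n
  shares
}

#' Proportion of the PRS effect explained by one endophenotype
#'
#' Compares the variance of the outcome explained by the PRS alone with the
#' PRS's LMG share once the endophenotype enters the model:
#' \code{1 - LMG_PRS(\{PRS, endo\}) / R2(outcome ~ PRS)}, clipped to [0, 1].
#' The unclipped value is attached as attribute \code{"raw"}. Undefined
#' (NA) when the marginal PRS R^2 is below 1e-6. A simpler semipartial
#' variant (\code{1 - (R2_both - R2_endo) / R2_PRS}) is available for
#' sensitivity analysis.
#'
#' @param outcome numeric vector (conventionally residualized on covariates).
#' @param prs numeric PRS vector.
#' @param endo numeric endophenotype vector.
#' @param method \code{"lmg"} (default) or \code{"semipartial"}.
#' @return clipped proportion in [0, 1] with attribute \code{"raw"}.
#' @export
proportion_explained <- function(outcome, prs, endo,
                                 method = c("lmg", "semipartial")) {
  method <- match.arg(method)
  X <- cbind(prs = prs, endo = endo)
  sub <- all_subset_r2(outcome, X)
  r2_prs <- sub$r2[2]     # mask 01 = {prs}
  r2_endo <- sub$r2[3]    # mask 10 = {endo}
  r2_both <- sub$r2[4]
  if (r2_prs < 1e-6) {
    out <- NA_real_
    attr(out, "raw") <- NA_real_
    return(out)
  }
  prs_share <- if (method == "lmg") {
    0.5 * r2_prs + 0.5 * (r2_both - r2_endo)
  } else {
    r2_both - r2_endo
  }
  raw <- 1 - prs_share / r2_prs
  out <- min(max(raw, 0), 1)
  attr(out, "raw") <- raw
  out
}

#' Proportion of the PRS effect explained by all endophenotypes jointly
#'
#' Same comparison with the full endophenotype set entered together: one
#' minus the ratio of the PRS's LMG share in the model \{PRS, endo_1..k\} to
#' the marginal PRS R^2, clipped to [0, 1].
#'
#' @param outcome numeric vector.
#' @param prs numeric PRS vector.
#' @param endos data.frame or matrix of endophenotypes (at most 11).
#' @return clipped proportion with attribute \code{"raw"}.
#' @export
joint_explained <- function(outcome, prs, endos) {
  X <- cbind(prs = prs, as.matrix(endos))
  shares <- lmg_decompose(outcome, X)
  r2_prs <- as.numeric(all_subset_r2(outcome, matrix(prs, ncol = 1))$r2[2])
  if (r2_prs < 1e-6) {
    out <- NA_real_
    attr(out, "raw") <- NA_real_
    return(out)
  }
  raw <- 1 - shares[["prs"]] / r2_prs
  out <- min(max(raw, 0), 1)
  attr(out, "raw") <- raw
  out
}

#' Mediation decomposition for one outcome over a set of endophenotypes
#'
#' Runs \code{\link{proportion_explained}} per endophenotype and
#' \code{\link{joint_explained}} over all of them, returning a tidy result
#' object.
#'
#' @param outcome numeric vector (residualized motor outcome).
#' @param prs numeric PRS vector.
#' @param endos data.frame/matrix of candidate mediators.
#' @param outcome_id label for printing.
#' @param method passed to \code{\link{proportion_explained}}.
#' @return object of class \code{mediation_result}: per-endophenotype table
#'   (marginal PRS R^2, LMG share, clipped and raw proportions) and the
#'   joint proportion.
#' @export
mediate <- function(outcome, prs, endos, outcome_id = "outcome",
                    method = c("lmg", "semipartial")) {
  method <- match.arg(method)
  endos <- as.matrix(endos)
  r2_prs <- as.numeric(all_subset_r2(outcome, matrix(prs, ncol = 1))$r2[2])
  rows <- lapply(colnames(endos), function(v) {
    pe <- proportion_explained(outcome, prs, endos[, v], method = method)
    data.frame(endophenotype = v, r2_prs_marginal = r2_prs,
               proportion = as.numeric(pe), proportion_raw = attr(pe, "raw"),
               stringsAsFactors = FALSE)
  })
  joint <- if (ncol(endos) <= 11) {
    joint_explained(outcome, prs, endos)
  } else {
    NA_real_
  }
  structure(list(outcome = outcome_id, per_endophenotype = do.call(rbind, rows),
                 joint = as.numeric(joint), joint_raw = attr(joint, "raw"),
                 method = method),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation_result for '%s' (%s metric)\n", x$outcome, x$method))
  df <- x$per_endophenotype
  df$proportion <- round(df$proportion, 3)
  df$r2_prs_marginal <- signif(df$r2_prs_marginal, 3)
  print(df[, c("endophenotype", "r2_prs_marginal", "proportion")],
        row.names = FALSE)
  cat(sprintf("  jointly explained: %.3f\n", x$joint))
  invisible(x)
}
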
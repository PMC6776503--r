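#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm glm binomial coef resid predict pnorm pt qnorm rnorm
#'   rbinom runif sd var cor complete.cases p.adjust phyper pbinom setNames
#'   quantile
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom MASS ginv
NULL

# Deterministic named random streams: every stochastic operation draws from
# a sub-seed derived from (base seed, stream name), so adding a downstream
# stage never perturbs the draws of an earlier one.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(seed) * 7919 + h) %% 2147480009)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(stream_seed(seed, stream))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

fail_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_range <- function(x, field, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    fail_field(field, "must be a single number")
  }
  ok <- (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    fail_field(field, sprintf(
      "must be in %s%s, %s%s", if (lo_open) "(" else "[", lo, hi,
      if (hi_open) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    fail_field(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

# z-scale a vector; zero-variance input is an error unless `name` is NULL
zscale <- function(x, name = NULL) {
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    stop(sprintf(
      "measure %s has zero variance; cannot standardize",
      if (is.null(name)) "" else shQuote(name)
    ), call. = FALSE)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}
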
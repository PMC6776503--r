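# Composite motor phenotyping: a global parkinsonism score from four
# clinician-rated signs, and a global motor score from ten performance tests.

PARKINSONIAN_SIGNS <- c("gait_sign", "bradykinesia_sign", "rigidity_sign",
                        "tremor_sign")

# ten performance measures and their orientation in raw units:
# TRUE  = higher raw value is better performance
# FALSE = higher raw value is worse (times and step counts)
MOTOR_MEASURES <- c(
  grip = TRUE, pinch = TRUE, pegboard = TRUE, tapping = TRUE,
  walk_time = FALSE, walk_steps = FALSE, turn_time = FALSE, turn_steps = FALSE,
  leg_stand = TRUE, toe_stand = TRUE
)

MOTOR_DOMAINS <- list(
  strength = c("grip", "pinch"),
  dexterity = c("pegboard", "tapping"),
  gait = c("walk_time", "walk_steps", "turn_time", "turn_steps")
  # no balance composite: the stand tests enter only the global score
)

#' Score global parkinsonism from the four sign ratings
#'
#' Each sign is rated 0-100. The global score is the mean of the available
#' signs, square-root transformed; parkinsonian gait is square-root
#' transformed on its own; bradykinesia and rigidity are dichotomized (0 when
#' the sign is absent, 1 when present); tremor is carried untransformed.
#' Higher scores indicate more severe parkinsonian impairment. Individuals
#' with all four signs missing get a missing global score.
#'
#' @param items data.frame with columns \code{gait_sign},
#'   \code{bradykinesia_sign}, \code{rigidity_sign}, \code{tremor_sign}
#'   (0-100, NA allowed).
#' @return data.frame with \code{global_parkinsonism}, \code{parkinsonian_gait}
#'   (both sqrt scale), \code{bradykinesia_binary}, \code{rigidity_binary},
#'   \code{tremor}.
#' @export
score_parkinsonism <- function(items) {
  miss <- setdiff(PARKINSONIAN_SIGNS, names(items))
  if (length(miss)) {
    stop("missing sign columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  signs <- as.matrix(items[, PARKINSONIAN_SIGNS])
  rng <- range(signs, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 100)) {
    stop("sign scores must lie in [0, 100]", call. = FALSE)
  }
  global <- sqrt(rowMeans(signs, na.rm = TRUE))
  global[rowSums(!is.na(signs)) == 0] <- NA_real_
  data.frame(
    global_parkinsonism = global,
    parkinsonian_gait = sqrt(signs[, "gait_sign"]),
    bradykinesia_binary = as.integer(signs[, "bradykinesia_sign"] > 0),
    rigidity_binary = as.integer(signs[, "rigidity_sign"] > 0),
    tremor = signs[, "tremor_sign"]
  )
}

#' Score the global motor composite from ten performance measures
#'
#' Each measure is oriented so that higher raw performance means better
#' function (times and step counts are negated), z-scaled over the cohort,
#' and averaged over the measures available for each individual. The sign of
#' the composite and of its domain summaries (strength, dexterity, gait) is
#' then reversed so a higher score indicates more severe motor impairment.
#' No balance composite is formed; the two stand tests contribute only to
#' the global score.
#'
#' @param items data.frame with the ten measure columns (grip, pinch,
#'   pegboard, tapping, walk_time, walk_steps, turn_time, turn_steps,
#'   leg_stand, toe_stand); NA allowed.
#' @return data.frame with \code{global_motor}, \code{strength},
#'   \code{dexterity}, \code{gait}, and attribute \code{"n_scored"} (cohort
#'   size the z-scaling was computed on).
#' @export
score_global_motor <- function(items) {
  miss <- setdiff(names(MOTOR_MEASURES), names(items))
  if (length(miss)) {
    stop("missing measure columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  z <- matrix(NA_real_, nrow(items), length(MOTOR_MEASURES),
              dimnames = list(NULL, names(MOTOR_MEASURES)))
  for (m in names(MOTOR_MEASURES)) {
    v <- items[[m]]
    if (sum(!is.na(v)) < 2) {
      stop(sprintf("measure '%s' needs >= 2 non-missing values", m),
           call. = FALSE)
    }
    v <- if (MOTOR_MEASURES[[m]]) v else -v
    z[, m] <- zscale(v, m)
  }
  avg <- function(cols) {
    zz <- z[, cols, drop = FALSE]
    out <- rowMeans(zz, na.rm = TRUE)
    out[rowSums(!is.na(zz)) == 0] <- NA_real_
    -out  # reversal: higher = more impaired
  }
  res <- data.frame(
    global_motor = avg(names(MOTOR_MEASURES)),
    strength = avg(MOTOR_DOMAINS$strength),
    dexterity = avg(MOTOR_DOMAINS$dexterity),
    gait = avg(MOTOR_DOMAINS$gait)
  )
  attr(res, "n_scored") <- nrow(items)
  res
}

#' Score all motor composites
#'
#' Convenience wrapper running \code{\link{score_parkinsonism}} and
#' \code{\link{score_global_motor}} on one item table.
#' @param items data.frame holding both the sign and performance columns.
#' @return data.frame with all composite and domain scores.
#' @export
score_motor <- function(items) {
  cbind(score_parkinsonism(items), score_global_motor(items))
}
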
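#' Convert a mean absolute deviation to a normal standard deviation
#'
#' For a normal distribution the mean absolute deviation equals
#' sd * sqrt(2/pi), so sd = mad * sqrt(pi/2). Used to turn reported mean
#' absolute posture-measurement errors into the angle standard deviations of
#' the stochastic model.
#'
#' @param mean_absolute_error nonnegative numeric (vectorized).
#' @return Standard deviation(s), same units.
#' @examples
#' mad_to_sd(1)  # 1.2533
#' @export
mad_to_sd <- function(mean_absolute_error) {
  if (any(mean_absolute_error < 0))
    stop("mean absolute error must be >= 0", call. = FALSE)
  mean_absolute_error * sqrt(pi / 2)
}

#' Describe a stochastic lifting scenario
#'
#' Joint angles and hand load are modelled as independent normal random
#' variables around their measured means; anthropometry is fixed.
#'
#' @param posture_means a [posture()] of mean angles (degrees).
#' @param posture_sds named numeric of per-angle SDs (degrees) with names
#'   `ankle, knee, torso, shoulder, elbow`; all >= 0.
#' @param hand_mass_mean_kg,hand_mass_sd_kg hand-load distribution (kg).
#' @param subject a [subject()].
#' @param n_iterations Monte Carlo sample size (default 1e6).
#' @param seed integer RNG seed.
#' @param table,coefficients,erector_moment_arm_m,gravity model constants,
#'   as in [linkage()].
#' @return An object of class `random_scenario`.
#' @export
random_scenario <- function(posture_means, posture_sds,
                            hand_mass_mean_kg, hand_mass_sd_kg,
                            subject,
                            n_iterations = 1e6, seed = 1L,
                            table = default_segment_table(),
                            coefficients = default_beta_coefficients(),
                            erector_moment_arm_m = 0.053,
                            gravity = 9.81) {
  stopifnot(inherits(posture_means, "posture_spec"), inherits(subject, "lift_subject"))
  need <- c("ankle", "knee", "torso", "shoulder", "elbow")
  if (!all(need %in% names(posture_sds)))
    stop("posture_sds must be named: ", paste(need, collapse = ", "), call. = FALSE)
  posture_sds <- posture_sds[need]
  if (any(posture_sds < 0) || hand_mass_sd_kg < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (hand_mass_mean_kg < 0) stop("hand mass mean must be >= 0", call. = FALSE)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  structure(list(posture_means = posture_means, posture_sds = posture_sds,
                 hand_mass_mean_kg = hand_mass_mean_kg,
                 hand_mass_sd_kg = hand_mass_sd_kg,
                 subject = subject, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), table = table,
                 coefficients = coefficients,
                 erector_moment_arm_m = erector_moment_arm_m,
                 gravity = gravity),
            class = "random_scenario")
}

#' Monte Carlo propagation through the linkage model
#'
#' Draws independent normal samples for the varied inputs (non-varied inputs
#' are held at their means), propagates every draw through the deterministic
#' statics pipeline, and returns a `sample_set`: a data.frame of per-draw
#' inputs and outputs with an importance-weight column (all 1 at this
#' stage). Each input variable uses its own RNG substream derived from the
#' scenario seed, so e.g. the hand-load draws are identical whether or not
#' posture is also varied. Hand-mass draws below zero (physically
#' impossible) are clamped to zero and counted in the
#' `n_clamped_hand_mass` attribute.
#'
#' @param scenario a [random_scenario()].
#' @param vary which inputs are random: "posture", "hand_load", "both" or
#'   "none".
#' @param n,seed optional overrides of the scenario's iteration count/seed.
#' @return A data.frame of class `sample_set` with columns
#'   `ankle_deg ... elbow_deg, hand_mass_kg, elbow_moment_nm,
#'   shoulder_moment_nm, l5s1_moment_nm, l5s1_fy_n, erector_force_n,
#'   disc_angle_deg, compression_n, shear_n, weight`; attributes `seed`,
#'   `vary`, `n_clamped_hand_mass`.
#' @export
simulate_lifting <- function(scenario, vary = c("both", "posture", "hand_load", "none"),
                             n = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "random_scenario"))
  vary <- match.arg(vary)
  n <- as.integer(if (is.null(n)) scenario$n_iterations else n)
  seed <- as.integer(if (is.null(seed)) scenario$seed else seed)
  if (n < 1) stop("n must be >= 1", call. = FALSE)

  # one substream per input variable, derived once from the master seed
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 6L)
  vary_posture <- vary %in% c("both", "posture")
  vary_hand <- vary %in% c("both", "hand_load")

  mu <- vapply(scenario$posture_means, `[`, numeric(1), 1)
  sds <- scenario$posture_sds
  draw <- function(k, mean, sd_) {
    if (sd_ == 0) return(rep.int(mean, n))
    set.seed(sub[k])
    rnorm(n, mean, sd_)
  }
  ang <- list(
    ankle_deg = if (vary_posture) draw(1L, mu[["ankle_deg"]], sds[["ankle"]]) else rep.int(mu[["ankle_deg"]], n),
    knee_deg = if (vary_posture) draw(2L, mu[["knee_deg"]], sds[["knee"]]) else rep.int(mu[["knee_deg"]], n),
    torso_deg = if (vary_posture) draw(3L, mu[["torso_deg"]], sds[["torso"]]) else rep.int(mu[["torso_deg"]], n),
    shoulder_deg = if (vary_posture) draw(4L, mu[["shoulder_deg"]], sds[["shoulder"]]) else rep.int(mu[["shoulder_deg"]], n),
    elbow_deg = if (vary_posture) draw(5L, mu[["elbow_deg"]], sds[["elbow"]]) else rep.int(mu[["elbow_deg"]], n)
  )
  hand <- if (vary_hand) draw(6L, scenario$hand_mass_mean_kg, scenario$hand_mass_sd_kg)
          else rep.int(scenario$hand_mass_mean_kg, n)
  n_clamped <- sum(hand < 0)
  if (n_clamped > 0) hand[hand < 0] <- 0

  pos <- structure(ang, class = "posture_spec")
  res <- linkage(pos, hand, scenario$subject, scenario$table,
                 scenario$coefficients, scenario$erector_moment_arm_m,
                 scenario$gravity)
  out <- cbind(as.data.frame(ang), hand_mass_kg = hand, as.data.frame(res),
               weight = rep.int(1, n))
  class(out) <- c("sample_set", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "vary") <- vary
  attr(out, "n_clamped_hand_mass") <- n_clamped
  out
}

#' Weighted summary of a sampled quantity
#'
#' Weighted mean, standard deviation, quartiles and effective sample size
#' ESS = (sum w)^2 / sum w^2 of one column of a `sample_set` (or of any
#' numeric vector with weights). Quantiles use the inverse weighted
#' empirical CDF (smallest x whose cumulative weight reaches p). The
#' variance uses weights normalised to sum to n with an (n - 1)-style
#' denominator, so uniform weights reproduce the unweighted [mean()], [sd()]
#' and type-1 [quantile()] exactly.
#'
#' @param samples a `sample_set` data.frame, or a numeric vector.
#' @param field column name when `samples` is a data.frame (e.g.
#'   "compression_n").
#' @param weights optional weights; defaults to the `weight` column (or 1s).
#' @return A list of class `weighted_summary` with `mean`, `sd`, `p25`,
#'   `p50`, `p75`, `ess`, `n`.
#' @export
summarize_samples <- function(samples, field = "compression_n", weights = NULL) {
  if (is.data.frame(samples)) {
    if (!field %in% names(samples))
      stop(sprintf("field '%s' not present in samples", field), call. = FALSE)
    x <- samples[[field]]
    if (is.null(weights)) weights <- samples[["weight"]]
  } else {
    x <- samples
  }
  n <- length(x)
  if (is.null(weights)) weights <- rep.int(1, n)
  if (length(weights) != n) stop("weights and samples differ in length", call. = FALSE)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  sw <- sum(weights)
  if (sw <= 0) stop("weights sum to zero: evidence impossible under the prior",
                    call. = FALSE)
  wn <- weights * (n / sw)
  m <- sum(wn * x) / n
  v <- if (n > 1) sum(wn * (x - m)^2) / (n - 1) else 0
  q <- weighted_quantile(x, weights, c(0.25, 0.5, 0.75))
  structure(list(mean = m, sd = sqrt(v),
                 p25 = q[[1]], p50 = q[[2]], p75 = q[[3]],
                 ess = sw^2 / sum(weights^2), n = n),
            class = "weighted_summary")
}

#' @export
print.weighted_summary <- function(x, digits = 2, ...) {
  cat(sprintf("mean %.*f  sd %.*f  p25 %.*f  median %.*f  p75 %.*f  (ESS %.0f of %d)\n",
              digits, x$mean, digits, x$sd, digits, x$p25, digits, x$p50,
              digits, x$p75, x$ess, x$n))
  invisible(x)
}

#' Weighted quantiles (inverse empirical CDF)
#'
#' Returns, for each probability p, the smallest sample value whose
#' normalised cumulative weight is at least p. With unit weights this is
#' `quantile(x, p, type = 1)`.
#'
#' @param x numeric sample.
#' @param weights nonnegative weights, same length as `x`.
#' @param probs probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, weights, probs) {
  if (any(probs < 0 | probs > 1)) stop("probs must be in [0, 1]", call. = FALSE)
  o <- order(x)
  cw <- cumsum(weights[o])
  tot <- cw[length(cw)]
  if (tot <= 0) stop("weights sum to zero", call. = FALSE)
  xs <- x[o]
  vapply(probs, function(p) {
    if (p == 0) return(xs[which(weights[o] > 0)[1]])
    xs[which(cw >= p * tot - tot * 1e-12)[1]]
  }, numeric(1))
}
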
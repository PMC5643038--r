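#' Disc compressive strength model
#'
#' Ultimate compressive strength of the L5/S1 disc, normally distributed;
#' the defaults (mean 5448 N, SD 2366 N) come from cadaver testing of spinal
#' motion segments in mild flexion. In the stress-strength interference
#' model, disc prolapse occurs if and only if the applied compression force
#' exceeds this strength. Strength is independent of every model input.
#'
#' @param mean_n,sd_n distribution parameters (N); `sd_n > 0`.
#' @return An object of class `strength_model`.
#' @export
strength_model <- function(mean_n = 5448, sd_n = 2366) {
  stopifnot(is.numeric(mean_n), is.numeric(sd_n))
  if (sd_n <= 0) stop("strength sd must be > 0", call. = FALSE)
  structure(list(mean_n = mean_n, sd_n = sd_n), class = "strength_model")
}

# per-draw probability that an independent normal strength is exceeded
.exceedance <- function(compression, strength) {
  pnorm((compression - strength$mean_n) / strength$sd_n)
}

#' Probability of disc injury under the prior
#'
#' The prolapse indicator is true iff compression exceeds strength, so the
#' (weighted) injury probability is the average over draws of
#' `pnorm((C_i - mu_s) / sigma_s)` — the analytic per-draw probability that
#' an independent normal strength is exceeded. No strength sampling is
#' involved, which removes one Monte Carlo variance source.
#'
#' @param samples a `sample_set` from [simulate_lifting()] (needs a
#'   `compression_n` column), or a numeric vector of compression values.
#' @param strength a [strength_model()].
#' @param weights optional prior weights (defaults to the `weight` column).
#' @return Scalar probability in `[0, 1]`.
#' @export
injury_probability <- function(samples, strength = strength_model(), weights = NULL) {
  if (is.data.frame(samples)) {
    if (!"compression_n" %in% names(samples))
      stop("samples lack a 'compression_n' column", call. = FALSE)
    if (is.null(weights)) weights <- samples[["weight"]]
    samples <- samples[["compression_n"]]
  }
  if (is.null(weights)) weights <- rep.int(1, length(samples))
  p <- .exceedance(samples, strength)
  sum(weights * p) / sum(weights)
}

#' Condition the sample set on disc-injury evidence
#'
#' Exact Bayesian updating by importance weighting: entering evidence that
#' the prolapse node is `"true"` multiplies each draw's weight by its
#' analytic probability of exceeding strength, `pnorm((C_i - mu_s)/sigma_s)`;
#' evidence `"false"` multiplies by the complement. The draws themselves are
#' untouched, so every downstream quantity (shear, moments, inputs) is
#' conditioned through the shared draws — the "trek" by which descendant
#' evidence propagates. `method = "sample"` instead draws one strength value
#' per sample and uses the 0/1 exceedance indicator (didactic parity with
#' the graph; higher variance).
#'
#' @param samples a `sample_set`.
#' @param strength a [strength_model()].
#' @param evidence one of "none", "true", "false".
#' @param method "analytic" (default) or "sample".
#' @param seed RNG seed used only by `method = "sample"`.
#' @return The `sample_set` with updated `weight` column.
#' @export
condition_on_injury <- function(samples, strength = strength_model(),
                                evidence = c("none", "true", "false"),
                                method = c("analytic", "sample"), seed = 1L) {
  evidence <- match.arg(evidence)
  method <- match.arg(method)
  if (evidence == "none") return(samples)
  if (!"compression_n" %in% names(samples))
    stop("samples lack a 'compression_n' column", call. = FALSE)
  p <- if (method == "analytic") {
    .exceedance(samples$compression_n, strength)
  } else {
    set.seed(seed)
    s <- rnorm(nrow(samples), strength$mean_n, strength$sd_n)
    as.numeric(samples$compression_n > s)
  }
  lik <- if (evidence == "true") p else 1 - p
  w <- samples$weight * lik
  if (sum(w) <= 0)
    stop("all importance weights are zero: evidence '", evidence,
         "' is impossible under the prior (prior injury probability ",
         signif(injury_probability(samples, strength), 4), ")", call. = FALSE)
  samples$weight <- w
  attr(samples, "evidence") <- evidence
  samples
}

#' Posterior summary given disc-injury evidence
#'
#' Composes [condition_on_injury()] and [summarize_samples()]. Warns when
#' the effective sample size drops below 1% of the number of draws (severely
#' informative evidence).
#'
#' @inheritParams condition_on_injury
#' @param field which output column to summarize (default compression).
#' @return A `weighted_summary`.
#' @export
posterior_summary <- function(samples, strength = strength_model(),
                              evidence = c("none", "true", "false"),
                              field = "compression_n",
                              method = c("analytic", "sample"), seed = 1L) {
  evidence <- match.arg(evidence)
  cond <- condition_on_injury(samples, strength, evidence, method, seed)
  s <- summarize_samples(cond, field)
  if (s$ess < 0.01 * s$n)
    warning(sprintf("effective sample size %.0f is below 1%% of n = %d", s$ess, s$n))
  s
}
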
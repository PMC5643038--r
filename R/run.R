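#' Run a configured scenario end to end
#'
#' Dispatches on the config's `mode`:
#' \describe{
#'   \item{deterministic}{one pass through [linkage()] at the mean inputs;}
#'   \item{mc}{seeded Monte Carlo via [simulate_lifting()] with weighted
#'     summaries of every output quantity;}
#'   \item{posterior}{as `mc`, then conditions on the config's disc-injury
#'     `evidence` via importance weighting and reports prior and posterior
#'     summaries plus the prior injury probability.}
#' }
#'
#' @param config a `scenario_config` (or a path to one).
#' @param quiet suppress the INFO banner.
#' @return An object of class `run_report`: list with `config`, `mode`,
#'   `seed`, `n`, `deterministic` (a `linkage_result`), and for stochastic
#'   modes `summaries` (data.frame: quantity, mean, sd, p25, p50, p75, ess),
#'   `injury_probability`, `posterior_summaries`, `evidence`.
#' @export
run_scenario <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_scenario_config(config)
  stopifnot(inherits(config, "scenario_config"))
  sc <- .scenario_from_config(config)
  det <- linkage(sc$posture_means, sc$hand_mass_mean_kg, sc$subject, sc$table,
                 sc$coefficients, sc$erector_moment_arm_m)
  rep_ <- list(config = config, mode = config$mode, seed = config$seed,
               n = config$n_iterations, deterministic = det,
               version = as.character(utils::packageVersion("liftbn")))
  if (!quiet)
    message(sprintf("liftbn: mode=%s n=%d seed=%d vary=%s evidence=%s",
                    config$mode, config$n_iterations, config$seed, config$vary,
                    config$evidence))
  if (config$mode != "deterministic") {
    samples <- simulate_lifting(sc, vary = config$vary)
    rep_$summaries <- .summary_table(samples)
    nc <- attr(samples, "n_clamped_hand_mass")
    if (!quiet && nc > 0)
      message(sprintf("liftbn: clamped %d negative hand-mass draw(s) to zero", nc))
    if (config$mode == "posterior") {
      str_ <- strength_model(config$strength$mean_n, config$strength$sd_n)
      rep_$injury_probability <- injury_probability(samples, str_)
      rep_$evidence <- config$evidence
      cond <- condition_on_injury(samples, str_, config$evidence)
      rep_$posterior_summaries <- .summary_table(cond)
      ess <- rep_$posterior_summaries$ess[1]
      if (!quiet && ess < 0.01 * nrow(cond))
        message(sprintf("liftbn: WARNING effective sample size %.0f < 1%% of n", ess))
    }
  }
  structure(rep_, class = "run_report")
}

.report_quantities <- c(elbow_moment_nm = "elbow_moment_nm",
                        shoulder_moment_nm = "shoulder_moment_nm",
                        l5s1_moment_nm = "l5s1_moment_nm",
                        compression_n = "compression_n",
                        shear_n = "shear_n")

.summary_table <- function(samples) {
  rows <- lapply(names(.report_quantities), function(q) {
    s <- summarize_samples(samples, q)
    data.frame(quantity = q, mean = s$mean, sd = s$sd, p25 = s$p25,
               p50 = s$p50, p75 = s$p75, ess = s$ess)
  })
  do.call(rbind, rows)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("liftbn run report (mode %s, seed %d, version %s)\n",
              x$mode, x$seed, x$version))
  cat("deterministic result at mean inputs:\n")
  det <- as.data.frame(x$deterministic)
  print(round(unlist(det[1, ]), 2))
  if (!is.null(x$summaries)) {
    cat(sprintf("\nMonte Carlo summaries (n = %d):\n", x$n))
    print(transform(x$summaries, mean = round(mean, 1), sd = round(sd, 1),
                    p25 = round(p25, 1), p50 = round(p50, 1),
                    p75 = round(p75, 1), ess = round(ess)), row.names = FALSE)
  }
  if (!is.null(x$injury_probability))
    cat(sprintf("\nprior disc-injury probability: %.4f\n", x$injury_probability))
  if (!is.null(x$posterior_summaries)) {
    cat(sprintf("posterior summaries given disc injury = %s:\n", x$evidence))
    print(transform(x$posterior_summaries, mean = round(mean, 1), sd = round(sd, 1),
                    p25 = round(p25, 1), p50 = round(p50, 1),
                    p75 = round(p75, 1), ess = round(ess)), row.names = FALSE)
  }
  invisible(x)
}

#' Write a run report as CSV
#'
#' Deterministic quantities are written as single-row summaries (sd and
#' percentiles equal to the point value); stochastic summaries as-is, with
#' a `stage` column distinguishing prior and posterior rows.
#'
#' @param report a `run_report`.
#' @param path output CSV path.
#' @return The written data.frame, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  det <- as.data.frame(report$deterministic)[1, ]
  out <- data.frame(stage = "deterministic",
                    quantity = names(.report_quantities),
                    mean = as.numeric(det[unname(.report_quantities)]),
                    sd = 0, p25 = NA_real_, p50 = NA_real_, p75 = NA_real_,
                    ess = NA_real_)
  out$p25 <- out$p50 <- out$p75 <- out$mean
  if (!is.null(report$summaries))
    out <- rbind(out, cbind(stage = "prior", report$summaries))
  if (!is.null(report$posterior_summaries))
    out <- rbind(out, cbind(stage = sprintf("posterior_%s", report$evidence),
                            report$posterior_summaries))
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
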
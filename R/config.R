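# Scenario configuration: plain-text JSON, degrees and kilograms at the
# boundary, SI everywhere inside. Unknown keys are rejected so typos fail
# loudly rather than silently falling back to defaults.

.config_keys_required <- c("subject", "posture", "hand_load")
.config_keys_optional <- c("erector_moment_arm_m", "beta_coefficients",
                           "segment_table", "strength", "n_iterations",
                           "seed", "mode", "vary", "evidence")
.posture_joints <- c("ankle", "knee", "torso", "shoulder", "elbow")

.config_defaults <- function() {
  list(erector_moment_arm_m = 0.053,
       beta_coefficients = as.list(default_beta_coefficients()),
       segment_table = NULL,
       strength = list(mean_n = 5448, sd_n = 2366),
       n_iterations = 1e6,
       seed = 1L,
       mode = "deterministic",
       vary = "both",
       evidence = "none")
}

#' Construct and validate a scenario configuration
#'
#' @param config a named list mirroring the config-file schema: required
#'   keys `subject` (`stature_m`, `body_mass_kg`), `posture` (per joint
#'   `ankle, knee, torso, shoulder, elbow`: `mean_deg` and optional
#'   `sd_deg`), `hand_load` (`mean_kg`, optional `sd_kg`); optional keys
#'   `erector_moment_arm_m`, `beta_coefficients`, `segment_table`
#'   (overrides, see [segment_table()]), `strength` (`mean_n`, `sd_n`),
#'   `n_iterations`, `seed`, `mode` (`deterministic|mc|posterior`), `vary`
#'   (`both|posture|hand_load|none`), `evidence` (`none|true|false`).
#' @return A validated list of class `scenario_config` with defaults filled
#'   in.
#' @export
scenario_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  unknown <- setdiff(names(config), c(.config_keys_required, .config_keys_optional))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  missing_keys <- setdiff(.config_keys_required, names(config))
  if (length(missing_keys))
    stop("missing required config key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(.config_defaults(), config)

  if (!all(c("stature_m", "body_mass_kg") %in% names(cfg$subject)))
    stop("config key 'subject' needs 'stature_m' and 'body_mass_kg'", call. = FALSE)
  miss <- setdiff(.posture_joints, names(cfg$posture))
  if (length(miss))
    stop("config key 'posture' is missing joint(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (j in .posture_joints) {
    if (!"mean_deg" %in% names(cfg$posture[[j]]))
      stop(sprintf("config key 'posture.%s' needs 'mean_deg'", j), call. = FALSE)
    if (is.null(cfg$posture[[j]]$sd_deg)) cfg$posture[[j]]$sd_deg <- 0
    if (cfg$posture[[j]]$sd_deg < 0)
      stop(sprintf("config key 'posture.%s.sd_deg' must be >= 0", j), call. = FALSE)
  }
  if (!"mean_kg" %in% names(cfg$hand_load))
    stop("config key 'hand_load' needs 'mean_kg'", call. = FALSE)
  if (is.null(cfg$hand_load$sd_kg)) cfg$hand_load$sd_kg <- 0
  cfg$mode <- match.arg(cfg$mode, c("deterministic", "mc", "posterior"))
  cfg$vary <- match.arg(cfg$vary, c("both", "posture", "hand_load", "none"))
  cfg$evidence <- match.arg(as.character(cfg$evidence), c("none", "true", "false"))
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_iterations <- as.integer(cfg$n_iterations)
  # construct the pieces once so invalid numbers fail at load time
  cfg$.subject <- subject(cfg$subject$stature_m, cfg$subject$body_mass_kg)
  cfg$.table <- segment_table(cfg$segment_table)
  cfg$.coefficients <- unlist(cfg$beta_coefficients)
  if (cfg$erector_moment_arm_m <= 0)
    stop("config key 'erector_moment_arm_m' must be > 0", call. = FALSE)
  structure(cfg, class = "scenario_config")
}

#' Read a scenario configuration file
#'
#' @param path path to a JSON scenario file.
#' @return A `scenario_config`.
#' @seealso [scenario_config()] for the schema;
#'   `system.file("extdata", "carbon_lifting.json", package = "liftbn")` for
#'   the packaged heavy-lift fixture.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  scenario_config(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE))
}

#' Write a scenario configuration file
#'
#' Serializes the user-facing part of a config (not the derived `.`-prefixed
#' objects) as JSON; `read_scenario_config()` on the result reproduces an
#' identical configuration.
#'
#' @param config a `scenario_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  keep <- names(config)[!startsWith(names(config), ".")]
  out <- config[keep]
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Path to the packaged lifting-scenario fixture
#'
#' The packaged scenario describes a heavy industrial lift (carbon chunks
#' in an aluminium smelter): hand load N(53.1, 12.8) kg, 161.8 cm / 65.6 kg
#' female, posture means/SDs measured from video with known assessment
#' error.
#'
#' @return File path of the JSON fixture.
#' @export
carbon_lifting_fixture <- function() {
  system.file("extdata", "carbon_lifting.json", package = "liftbn", mustWork = TRUE)
}

# random_scenario from a validated config
.scenario_from_config <- function(cfg) {
  pm <- posture(cfg$posture$ankle$mean_deg, cfg$posture$knee$mean_deg,
                cfg$posture$torso$mean_deg, cfg$posture$shoulder$mean_deg,
                cfg$posture$elbow$mean_deg)
  sds <- vapply(.posture_joints, function(j) cfg$posture[[j]]$sd_deg, numeric(1))
  random_scenario(pm, sds, cfg$hand_load$mean_kg, cfg$hand_load$sd_kg,
                  cfg$.subject, cfg$n_iterations, cfg$seed, cfg$.table,
                  cfg$.coefficients, cfg$erector_moment_arm_m)
}
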
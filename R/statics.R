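#' Specify a lifting posture
#'
#' Five sagittal segment angles measured from the horizontal, in degrees:
#' ankle (shank direction), knee (thigh direction), torso (L5/S1-to-shoulder
#' link), shoulder (shoulder-to-elbow link) and elbow (forearm/hand line).
#' Angles may be negative or exceed 180 degrees; in the packaged heavy-lift
#' posture the elbow is at -56 and the shoulder at 192 degrees.
#'
#' @param ankle_deg,knee_deg,torso_deg,shoulder_deg,elbow_deg angles from
#'   horizontal (degrees). Each may be a vector; they are recycled to a
#'   common length.
#' @return An object of class `posture_spec`.
#' @export
posture <- function(ankle_deg, knee_deg, torso_deg, shoulder_deg, elbow_deg) {
  ang <- list(ankle_deg = ankle_deg, knee_deg = knee_deg, torso_deg = torso_deg,
              shoulder_deg = shoulder_deg, elbow_deg = elbow_deg)
  if (any(!vapply(ang, is.numeric, logical(1))) ||
      any(vapply(ang, function(a) any(!is.finite(a)), logical(1))))
    stop("all posture angles must be finite numerics", call. = FALSE)
  n <- max(lengths(ang))
  structure(lapply(ang, rep_len, n), class = "posture_spec")
}

#' @export
print.posture_spec <- function(x, ...) {
  cat("<posture (deg from horizontal)>\n")
  print(vapply(unclass(x), `[`, numeric(1), 1))
  invisible(x)
}

.deg2rad <- function(d) d * pi / 180

# Per-side distal loads hanging from the elbow: half the hand load plus the
# hand segment (both lumped at the grip centre, i.e. the hand COM on the
# forearm line) and the forearm segment at its COM.
.arm_levers <- function(anthro) {
  list(grip = anthro$lengths[["forearm"]] + anthro$coms[["hand"]],
       fa_com = anthro$coms[["forearm"]])
}

#' Elbow reaction load (per side)
#'
#' Top-down statics at the elbow: the reaction force equals the supported
#' weight (half the hand load plus hand and forearm segments, per side,
#' downward) and the reaction moment balances those gravity loads about the
#' elbow through the horizontal offsets implied by the elbow angle. The sign
#' convention is that loads anterior to (forward of) the joint give a
#' positive moment.
#'
#' @param posture a [posture()].
#' @param hand_load_kg total mass in the hands, kg (split between hands); may
#'   be a vector.
#' @param anthro resolved anthropometry from [resolve_anthropometry()].
#' @return A list of class `joint_load` with `fx`, `fy` (N, force exerted by
#'   the distal segments on the joint; gravity-only, so `fx = 0`) and
#'   `moment` (N m). Vectorized over posture/load.
#' @export
elbow_load <- function(posture, hand_load_kg, anthro) {
  stopifnot(inherits(posture, "posture_spec"))
  if (any(hand_load_kg < 0)) stop("hand load must be >= 0", call. = FALSE)
  ce <- cos(.deg2rad(posture$elbow_deg))
  lv <- .arm_levers(anthro)
  p2 <- hand_load_kg * anthro$gravity / 2
  w_h <- anthro$weights[["hand"]]
  w_fa <- anthro$weights[["forearm"]]
  m <- (p2 + w_h) * lv$grip * ce + w_fa * lv$fa_com * ce
  structure(list(fx = 0 * m, fy = -(p2 + w_h + w_fa), moment = m),
            class = "joint_load")
}

#' Shoulder reaction load (per side)
#'
#' Propagates the elbow reaction plus the upper-arm gravity load across the
#' upper-arm link. With the packaged posture the elbow lies posterior to the
#' shoulder (shoulder angle 192 degrees), so the shoulder moment is negative
#' under the anterior-positive convention.
#'
#' @param elbow a `joint_load` from [elbow_load()].
#' @inheritParams elbow_load
#' @return A `joint_load` (per side).
#' @export
shoulder_load <- function(elbow, posture, anthro) {
  cs <- cos(.deg2rad(posture$shoulder_deg))
  lu <- anthro$lengths[["upper_arm"]]
  w_ua <- anthro$weights[["upper_arm"]]
  # chain rule of top-down statics: carry the distal reaction across the
  # link, add the link's own gravity moment about the proximal joint
  m <- elbow$moment + (-elbow$fy) * lu * cs + w_ua * anthro$coms[["upper_arm"]] * cs
  structure(list(fx = elbow$fx, fy = elbow$fy - w_ua, moment = m),
            class = "joint_load")
}

#' L5/S1 reaction load
#'
#' Doubles the (bilaterally symmetric) shoulder loads and carries them, plus
#' the lumped head+neck+trunk gravity load, across the torso link to the
#' L5/S1 disc.
#'
#' @param shoulder a per-side `joint_load` from [shoulder_load()].
#' @inheritParams elbow_load
#' @return A `joint_load` for the whole body above L5/S1.
#' @export
l5s1_load <- function(shoulder, posture, anthro) {
  ct <- cos(.deg2rad(posture$torso_deg))
  lt <- anthro$lengths[["torso"]]
  w_t <- anthro$weights[["torso"]]
  m <- 2 * (shoulder$moment + (-shoulder$fy) * lt * ct) +
    w_t * anthro$coms[["torso"]] * ct
  structure(list(fx = 2 * shoulder$fx, fy = 2 * shoulder$fy - w_t, moment = m),
            class = "joint_load")
}

#' Default disc-angle regression coefficients
#'
#' The L5/S1 disc inclination is modelled as 40 degrees plus a deviation
#' `beta` predicted by a quadratic regression in T (torso angle from
#' vertical, degrees) and K (included knee angle, degrees):
#' `beta = b0 + bT*T + bK*K + bTK*T*K + bT2*T^2 + bK2*K^2`.
#' The default coefficients are the classic pelvic-rotation regression used
#' by sagittal lifting models; they are a reconstruction (the source
#' coefficients are not printed alongside the worked example this package is
#' calibrated against) and are fully overridable via config.
#'
#' @return Named numeric vector `b0, bT, bK, bTK, bT2, bK2`.
#' @export
default_beta_coefficients <- function() {
  c(b0 = -17.5, bT = -0.12, bK = 0.23, bTK = 0.0012, bT2 = 0.005, bK2 = -0.00075)
}

#' Disc inclination from posture
#'
#' Computes T = 90 - torso angle (from-vertical conversion), the included
#' knee angle K = 180 - (knee angle - ankle angle) (interior angle between
#' thigh and shank directions), the regression deviation `beta`, and the
#' disc angle 40 + beta (degrees from horizontal).
#'
#' @inheritParams elbow_load
#' @param coefficients named regression coefficients; see
#'   [default_beta_coefficients()].
#' @param erector_moment_arm_m erector spinae moment arm, metres (default
#'   0.053, the recommended value for models excluding intra-abdominal
#'   pressure).
#' @return A list of class `disc_geometry` with `T_deg`, `K_deg`, `beta_deg`,
#'   `disc_angle_deg` and `erector_moment_arm_m`.
#' @export
disc_angle <- function(posture, coefficients = default_beta_coefficients(),
                       erector_moment_arm_m = 0.053) {
  need <- c("b0", "bT", "bK", "bTK", "bT2", "bK2")
  if (!all(need %in% names(coefficients)))
    stop("missing beta regression coefficient(s): ",
         paste(setdiff(need, names(coefficients)), collapse = ", "), call. = FALSE)
  if (erector_moment_arm_m <= 0)
    stop("erector moment arm must be > 0", call. = FALSE)
  Tv <- 90 - posture$torso_deg
  K <- 180 - (posture$knee_deg - posture$ankle_deg)
  b <- coefficients
  beta <- b[["b0"]] + b[["bT"]] * Tv + b[["bK"]] * K + b[["bTK"]] * Tv * K +
    b[["bT2"]] * Tv^2 + b[["bK2"]] * K^2
  structure(list(T_deg = Tv, K_deg = K, beta_deg = beta,
                 disc_angle_deg = 40 + beta,
                 erector_moment_arm_m = erector_moment_arm_m),
            class = "disc_geometry")
}

#' Erector spinae force
#'
#' The net L5/S1 moment is balanced by a single equivalent extensor acting
#' at a fixed moment arm, so the muscle force is |moment| / arm.
#'
#' @param l5s1 a `joint_load` from [l5s1_load()].
#' @param moment_arm_m erector spinae moment arm (m), > 0.
#' @return Muscle force in newtons (vectorized).
#' @export
erector_force <- function(l5s1, moment_arm_m = 0.053) {
  if (moment_arm_m <= 0) stop("erector moment arm must be > 0", call. = FALSE)
  abs(l5s1$moment) / moment_arm_m
}

#' Resolve the L5/S1 reaction into disc compression and shear
#'
#' The reaction force is rotated into the disc frame: the disc plane is
#' inclined `disc_angle` degrees from the horizontal, so its normal is tilted
#' the same angle from the vertical. Compression is the erector spinae force
#' (whose line of action is perpendicular to the disc, contributing no
#' shear) plus the component of the reaction along the disc normal; shear is
#' the tangential component of the reaction alone.
#'
#' @param l5s1 a `joint_load`.
#' @param erector erector spinae force (N), from [erector_force()].
#' @param disc a `disc_geometry` from [disc_angle()].
#' @return A list with `compression_n` and `shear_n` (vectorized).
#' @export
compression_shear <- function(l5s1, erector, disc) {
  a <- .deg2rad(disc$disc_angle_deg)
  # disc normal (pointing up-forward) and down-slope tangent unit vectors
  normal <- -(l5s1$fx * sin(a) + l5s1$fy * cos(a))  # compressive onto the disc
  shear <- l5s1$fx * cos(a) - l5s1$fy * sin(a)
  list(compression_n = erector + normal, shear_n = shear)
}

#' Run the full deterministic linkage model
#'
#' Chains [elbow_load()], [shoulder_load()], [l5s1_load()], [disc_angle()],
#' [erector_force()] and [compression_shear()] for one (or a vector of)
#' input realisation(s).
#'
#' @inheritParams elbow_load
#' @param subject a [subject()].
#' @param table segment table; defaults to the calibrated table.
#' @param coefficients disc-angle regression coefficients.
#' @param erector_moment_arm_m erector spinae moment arm (m).
#' @param gravity gravitational acceleration (m/s^2).
#' @return For scalar inputs, a `linkage_result` (a list with `elbow`,
#'   `shoulder`, `l5s1` joint loads, `erector_force_n`, `disc`,
#'   `compression_n`, `shear_n`); all numeric leaves are vectorized when the
#'   inputs are vectors.
#' @examples
#' res <- linkage(posture(82, 114, 40, 192, -56), 53.1, subject(1.618, 65.6))
#' res$l5s1$moment       # ~150.9 N m
#' res$compression_n     # ~3316 N
#' @export
linkage <- function(posture, hand_load_kg, subject,
                    table = default_segment_table(),
                    coefficients = default_beta_coefficients(),
                    erector_moment_arm_m = 0.053,
                    gravity = 9.81) {
  anthro <- resolve_anthropometry(subject, table, gravity)
  el <- elbow_load(posture, hand_load_kg, anthro)
  sh <- shoulder_load(el, posture, anthro)
  l5 <- l5s1_load(sh, posture, anthro)
  disc <- disc_angle(posture, coefficients, erector_moment_arm_m)
  es <- erector_force(l5, erector_moment_arm_m)
  cshear <- compression_shear(l5, es, disc)
  structure(list(elbow = el, shoulder = sh, l5s1 = l5,
                 erector_force_n = es, disc = disc,
                 compression_n = cshear$compression_n,
                 shear_n = cshear$shear_n),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, digits = 1, ...) {
  cat("<linkage result>\n")
  df <- as.data.frame(x)
  if (nrow(df) == 1) {
    print(round(unlist(df[1, ]), digits))
  } else {
    cat(sprintf("  %d realisations; first rows:\n", nrow(df)))
    print(round(utils::head(df, 3), digits))
  }
  invisible(x)
}

#' @export
as.data.frame.linkage_result <- function(x, ...) {
  data.frame(elbow_moment_nm = x$elbow$moment,
             shoulder_moment_nm = x$shoulder$moment,
             l5s1_moment_nm = x$l5s1$moment,
             l5s1_fy_n = x$l5s1$fy,
             erector_force_n = x$erector_force_n,
             disc_angle_deg = x$disc$disc_angle_deg,
             compression_n = x$compression_n,
             shear_n = x$shear_n)
}

#' One-shot free-body moment summation (verification oracle)
#'
#' Computes the gravity moment of every load distal to a joint about that
#' joint directly from absolute sagittal positions, without the top-down
#' chaining used by [elbow_load()] and friends. Intended as an independent
#' equilibrium check: the two routes must agree to floating precision.
#'
#' @inheritParams linkage
#' @param joint one of "elbow", "shoulder", "l5s1".
#' @return Moment in N m (vectorized), anterior-positive.
#' @export
free_body_moment <- function(joint = c("elbow", "shoulder", "l5s1"),
                             posture, hand_load_kg, subject,
                             table = default_segment_table(),
                             gravity = 9.81) {
  joint <- match.arg(joint)
  anthro <- resolve_anthropometry(subject, table, gravity)
  ce <- cos(.deg2rad(posture$elbow_deg))
  cs <- cos(.deg2rad(posture$shoulder_deg))
  ct <- cos(.deg2rad(posture$torso_deg))
  lv <- .arm_levers(anthro)
  # horizontal positions relative to L5/S1
  x_sh <- anthro$lengths[["torso"]] * ct
  x_el <- x_sh + anthro$lengths[["upper_arm"]] * cs
  x_grip <- x_el + lv$grip * ce
  x_fa <- x_el + lv$fa_com * ce
  x_ua <- x_sh + anthro$coms[["upper_arm"]] * cs
  x_torso <- anthro$coms[["torso"]] * ct
  p2 <- hand_load_kg * gravity / 2
  w_h <- anthro$weights[["hand"]]
  w_fa <- anthro$weights[["forearm"]]
  w_ua <- anthro$weights[["upper_arm"]]
  w_t <- anthro$weights[["torso"]]
  x0 <- switch(joint, elbow = x_el, shoulder = x_sh, l5s1 = 0)
  arm_m <- (p2 + w_h) * (x_grip - x0) + w_fa * (x_fa - x0)
  if (joint == "elbow") return(arm_m)
  arm_m <- arm_m + w_ua * (x_ua - x0)
  if (joint == "shoulder") return(arm_m)
  2 * arm_m + w_t * (x_torso - x0)
}
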
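#' Define a subject by stature and body mass
#'
#' The model scales all body-segment lengths from stature and all segment
#' masses from total body mass, in the tradition of the classic
#' occupational-biomechanics link-segment tables.
#'
#' @param stature_m standing height in metres; must be positive.
#' @param body_mass_kg total body mass in kilograms; must be positive.
#' @return An object of class `lift_subject`.
#' @examples
#' subject(1.618, 65.6)  # 50th-percentile female
#' @export
subject <- function(stature_m, body_mass_kg) {
  stopifnot(is.numeric(stature_m), length(stature_m) == 1L, is.finite(stature_m),
            is.numeric(body_mass_kg), length(body_mass_kg) == 1L, is.finite(body_mass_kg))
  if (stature_m <= 0) stop("`stature_m` must be > 0", call. = FALSE)
  if (body_mass_kg <= 0) stop("`body_mass_kg` must be > 0", call. = FALSE)
  structure(list(stature_m = stature_m, body_mass_kg = body_mass_kg),
            class = "lift_subject")
}

#' @export
print.lift_subject <- function(x, ...) {
  cat(sprintf("<subject: stature %.3f m, body mass %.1f kg>\n",
              x$stature_m, x$body_mass_kg))
  invisible(x)
}

# Segments recognised by the default table. "torso" is the lumped
# head + neck + trunk mass supported above the L5/S1 disc and its length is
# the L5/S1-to-shoulder link; "pelvis" carries the remaining trunk mass below
# L5/S1. Limb segments (hand, forearm, upper_arm, thigh, shank, foot) are
# per-side: the model is bilaterally symmetric, so each contributes twice to
# whole-body mass and the hand load is split equally between hands.
.liftbn_segments <- c("hand", "forearm", "upper_arm", "torso", "pelvis",
                      "thigh", "shank", "foot")
.liftbn_bilateral <- c("hand", "forearm", "upper_arm", "thigh", "shank", "foot")

#' Default body-segment parameter table
#'
#' Length fractions of stature, mass fractions of body mass and
#' centre-of-mass fractions of segment length (measured from the proximal
#' joint) for the eight-segment sagittal model. Mass and COM proportions for
#' the limbs follow the classic cadaver-derived values (Dempster tradition);
#' the forearm, upper-arm and torso *link* lengths and the torso/pelvis mass
#' split are **calibrated reconstructions**: the underlying textbook
#' constants are not public in a single authoritative form, so the defaults
#' were solved once so that the deterministic pipeline reproduces the
#' published worked example of the model (joint moments and disc forces for
#' a 161.8 cm / 65.6 kg subject lifting 53.1 kg) and then frozen. All values
#' can be overridden via [segment_table()] or the scenario config.
#'
#' @return A data.frame with columns `segment`, `length_fraction`,
#'   `mass_fraction`, `com_fraction` and a logical `bilateral` column.
#' @export
default_segment_table <- function() {
  data.frame(
    segment = .liftbn_segments,
    # forearm/upper_arm/torso link fractions calibrated (see above); others
    # are standard stature proportions.
    length_fraction = c(0.108, 0.125023, 0.184794, 0.253181, 0.078,
                        0.245, 0.246, 0.152),
    # torso/pelvis split calibrated; limbs are Dempster mass fractions.
    mass_fraction = c(0.006, 0.017, 0.028, 0.374981, 0.201019,
                      0.100, 0.0465, 0.0145),
    com_fraction = c(0.506, 0.430, 0.436, 0.600, 0.500,
                     0.433, 0.433, 0.429),
    bilateral = .liftbn_segments %in% .liftbn_bilateral,
    stringsAsFactors = FALSE
  )
}

#' Build or override a segment parameter table
#'
#' @param overrides optional named list; each element is itself a list (or
#'   named numeric) with any of `length_fraction`, `mass_fraction`,
#'   `com_fraction` for one segment, e.g.
#'   `list(forearm = list(length_fraction = 0.146))`.
#' @return A validated segment table (see [default_segment_table()]).
#' @export
segment_table <- function(overrides = NULL) {
  tab <- default_segment_table()
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("segment table overrides must be a named list", call. = FALSE)
    for (seg in names(overrides)) {
      i <- match(seg, tab$segment)
      if (is.na(i))
        stop(sprintf("unknown segment '%s' in table override", seg), call. = FALSE)
      ov <- overrides[[seg]]
      bad <- setdiff(names(ov), c("length_fraction", "mass_fraction", "com_fraction"))
      if (length(bad))
        stop(sprintf("unknown segment field(s) for '%s': %s",
                     seg, paste(bad, collapse = ", ")), call. = FALSE)
      for (f in names(ov)) tab[[f]][i] <- as.numeric(ov[[f]])
    }
  }
  validate_segment_table(tab)
  tab
}

#' Validate a segment parameter table
#'
#' Checks that all fractions lie in (0, 1) and that whole-body mass
#' fractions (bilateral segments counted twice) sum to 1 within 0.02.
#'
#' @param table a segment table data.frame.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_segment_table <- function(table) {
  need <- c("segment", "length_fraction", "mass_fraction", "com_fraction", "bilateral")
  if (!all(need %in% names(table)))
    stop("segment table is missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "), call. = FALSE)
  unknown <- setdiff(table$segment, .liftbn_segments)
  if (length(unknown))
    stop("unknown segment name(s) in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing_seg <- setdiff(.liftbn_segments, table$segment)
  if (length(missing_seg))
    stop("segment table is missing segment(s): ",
         paste(missing_seg, collapse = ", "), call. = FALSE)
  for (f in c("length_fraction", "mass_fraction", "com_fraction")) {
    v <- table[[f]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0) || any(v >= 1))
      stop(sprintf("segment table column '%s' must lie strictly in (0, 1)", f),
           call. = FALSE)
  }
  total <- sum(table$mass_fraction * ifelse(table$bilateral, 2, 1))
  if (abs(total - 1) > 0.02)
    stop(sprintf("whole-body mass fractions sum to %.4f; must be 1 +/- 0.02", total),
         call. = FALSE)
  invisible(table)
}

#' Segment lengths scaled from stature
#'
#' @param subject a [subject()].
#' @param table a segment table; defaults to [default_segment_table()].
#' @return Named numeric vector of segment lengths in metres.
#' @export
segment_lengths <- function(subject, table = default_segment_table()) {
  stopifnot(inherits(subject, "lift_subject"))
  validate_segment_table(table)
  setNames(subject$stature_m * table$length_fraction, table$segment)
}

#' Segment masses scaled from body mass
#'
#' Bilateral segments (hand, forearm, upper arm, thigh, shank, foot) are
#' reported per side.
#'
#' @inheritParams segment_lengths
#' @return Named numeric vector of per-segment masses in kilograms.
#' @export
segment_masses <- function(subject, table = default_segment_table()) {
  stopifnot(inherits(subject, "lift_subject"))
  validate_segment_table(table)
  setNames(subject$body_mass_kg * table$mass_fraction, table$segment)
}

#' Segment centre-of-mass locations
#'
#' @param lengths named vector of segment lengths (m), as returned by
#'   [segment_lengths()].
#' @param table a segment table.
#' @return Named numeric vector of COM distances from the proximal joint (m).
#' @export
segment_com <- function(lengths, table = default_segment_table()) {
  validate_segment_table(table)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("segment lengths must be positive and finite", call. = FALSE)
  idx <- match(table$segment, names(lengths))
  if (any(is.na(idx)))
    stop("lengths are missing segment(s): ",
         paste(table$segment[is.na(idx)], collapse = ", "), call. = FALSE)
  setNames(lengths[idx] * table$com_fraction, table$segment)
}

#' Resolve all anthropometric quantities for a subject
#'
#' Convenience wrapper returning lengths, per-side masses, gravity loads and
#' COM offsets in one list, as consumed by the statics layer.
#'
#' @inheritParams segment_lengths
#' @param gravity gravitational acceleration, m/s^2.
#' @return A list with elements `lengths` (m), `masses` (kg), `weights` (N),
#'   `coms` (m from proximal joint), `subject` and `table`.
#' @export
resolve_anthropometry <- function(subject, table = default_segment_table(),
                                  gravity = 9.81) {
  lengths <- segment_lengths(subject, table)
  masses <- segment_masses(subject, table)
  list(lengths = lengths,
       masses = masses,
       weights = masses * gravity,
       coms = segment_com(lengths, table),
       gravity = gravity,
       subject = subject,
       table = table)
}

#' Export resolved per-segment parameters as CSV
#'
#' @inheritParams segment_lengths
#' @param path file path to write.
#' @return The resolved data.frame, invisibly.
#' @export
export_segment_csv <- function(subject, table = default_segment_table(), path) {
  a <- resolve_anthropometry(subject, table)
  out <- data.frame(segment = table$segment,
                    length_m = as.numeric(a$lengths),
                    mass_kg = as.numeric(a$masses),
                    com_from_proximal_m = as.numeric(a$coms),
                    bilateral = table$bilateral)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
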
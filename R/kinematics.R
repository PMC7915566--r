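# Sagittal joint and pelvis angles, angular velocities and jump height
# from marker trajectories.
#
# Angle conventions (degrees): knee flexion positive, 0 = full extension;
# hip flexion positive relative to the pelvis line; ankle dorsiflexion
# positive, 0 at neutral standing (calibrated from the subject's static
# trial); anterior pelvic tilt positive when the anterior pelvis markers
# sit lower than the posterior ones. See the forward-kinematics module for
# the shared segment-orientation definitions.

signed_angle_from_vertical <- function(dx, dy) atan2(dx, dy) / DEG2RAD

segment_check <- function(v, name) {
  len2 <- rowSums(v^2)
  bad <- which(len2 < 1e-12)
  if (length(bad) > 0)
    stop("degenerate ", name, " segment (zero length) at frame ", bad[1])
  invisible(NULL)
}

#' Sagittal joint and pelvis angles from markers
#'
#' Computes pelvis anterior tilt, hip flexion, knee flexion and ankle angle
#' (all in degrees) for one body side from the planar marker set. Expects a
#' filtered trial; the ankle neutral offset should come from the subject's
#' static trial via `ankle_offset` (see [ankle_neutral_offset()]).
#'
#' @param trial a `trial_recording` (markers filtered)
#' @param side `"right"` or `"left"`
#' @param ankle_offset neutral-standing ankle angle to subtract, deg
#' @return data frame with columns `time`, `pelvis`, `hip`, `knee`, `ankle`
#' @export
joint_angles <- function(trial, side = c("right", "left"),
                         ankle_offset = 0) {
  side <- match.arg(side)
  pre <- if (side == "right") "R" else "L"
  hip <- marker_xy(trial, paste0(pre, "HIP"))
  kne <- marker_xy(trial, paste0(pre, "KNE"))
  ank <- marker_xy(trial, paste0(pre, "ANK"))
  hee <- marker_xy(trial, paste0(pre, "HEE"))
  toe <- marker_xy(trial, paste0(pre, "TOE"))
  ant <- (marker_xy(trial, "RASI") + marker_xy(trial, "LASI")) / 2
  pos <- (marker_xy(trial, "RPSI") + marker_xy(trial, "LPSI")) / 2

  segment_check(kne - ank, "shank")
  segment_check(hip - kne, "thigh")
  segment_check(toe - hee, "foot")
  segment_check(ant - pos, "pelvis")

  phi_s <- signed_angle_from_vertical(kne[, 1] - ank[, 1], kne[, 2] - ank[, 2])
  phi_t <- signed_angle_from_vertical(-(hip[, 1] - kne[, 1]), hip[, 2] - kne[, 2])
  phi_f <- atan2(toe[, 2] - hee[, 2], toe[, 1] - hee[, 1]) / DEG2RAD
  pelvis <- -atan2(ant[, 2] - pos[, 2], ant[, 1] - pos[, 1]) / DEG2RAD

  n <- nrow(hip)
  data.frame(
    time = (seq_len(n) - 1) / trial$rate_kin,
    pelvis = pelvis,
    hip = phi_t + pelvis,
    knee = phi_s + phi_t,
    ankle = phi_s + phi_f - ankle_offset
  )
}

#' Neutral ankle offset from a static trial
#'
#' Mean raw shank-foot angle over the standing trial; subtracting it
#' references the ankle angle to the subject's neutral standing posture
#' (dorsiflexion positive).
#'
#' @param static_trial a static `trial_recording`
#' @param side body side
#' @return offset in degrees
#' @export
ankle_neutral_offset <- function(static_trial, side = c("right", "left")) {
  side <- match.arg(side)
  ang <- joint_angles(static_trial, side = side, ankle_offset = 0)
  mean(ang$ankle)
}

#' Joint angular velocities
#'
#' First derivative (central differences) of each angle column, deg/s.
#'
#' @param angles data frame from [joint_angles()]
#' @param rate kinematic sampling rate, Hz
#' @return data frame with the same angle columns, in deg/s
#' @export
angular_velocity <- function(angles, rate) {
  out <- angles
  for (col in c("pelvis", "hip", "knee", "ankle"))
    out[[col]] <- derivative(angles[[col]], rate, order = 1)
  out
}

mean_pelvis_height <- function(trial) {
  (trial$markers$RASI[, 2] + trial$markers$LASI[, 2] +
     trial$markers$RPSI[, 2] + trial$markers$LPSI[, 2]) / 4
}

#' Jump height from pelvis markers
#'
#' Vertical displacement of the pelvis (average of the four pelvis markers)
#' between static standing and the peak height reached in the flight phase
#' after the analyzed contact, in cm.
#'
#' @param dvj_trial the jump `trial_recording`
#' @param static_trial the subject's static `trial_recording`
#' @param events a [detect_events()] result for `dvj_trial` (detected on
#'   the raw trial); if `NULL`, events are detected here
#' @return jump height in cm
#' @export
jump_height <- function(dvj_trial, static_trial, events = NULL) {
  if (is.null(events)) events <- detect_events(dvj_trial)
  y <- mean_pelvis_height(dvj_trial)
  flight <- seq_along(y) > events$idx_takeoff_kin
  if (!any(flight))
    stop("no flight phase after the analyzed contact")
  y_static <- mean(mean_pelvis_height(static_trial))
  (max(y[flight]) - y_static) * 100
}
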
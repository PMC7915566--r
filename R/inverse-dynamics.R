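# Planar bottom-up Newton-Euler inverse dynamics.
#
# Per segment (foot -> shank -> thigh), the Newton equation
# (sum F = m a_com) gives the proximal joint reaction force and the Euler
# equation about the segment CoM (sum M = I alpha) the net internal joint
# moment, given the distal loads (GRF applied at the COP for the foot).
#
# z-moments are scalar cross products in the sagittal plane
# (counter-clockwise positive with x anterior, y up). Reported moments
# follow the clinical convention: internal ankle plantarflexion, knee
# extension and hip extension moments positive. With these and anatomical
# angle rates, joint power M * omega is positive for generation
# (concentric) and negative for absorption (eccentric).

cross_z <- function(rx, ry, fx, fy) rx * fy - ry * fx

segment_kinematics <- function(prox, dist, com_fraction, rate) {
  com <- prox + com_fraction * (dist - prox)
  ang <- atan2(dist[, 2] - prox[, 2], dist[, 1] - prox[, 1])
  list(
    com = com,
    acc = cbind(derivative(com[, 1], rate, 2), derivative(com[, 2], rate, 2)),
    alpha = derivative(ang, rate, 2)
  )
}

#' Planar Newton-Euler inverse dynamics for one leg
#'
#' Bottom-up recursion foot, shank, thigh using filtered marker kinematics
#' and the leg's plate GRF (already filtered and decimated to the kinematic
#' rate). Returns net internal joint moments (raw and body-mass
#' normalized), joint reaction forces, and the plate vertical GRF in
#' multiples of body weight.
#'
#' @param trial a `trial_recording` with filtered markers
#' @param model a [build_body_model()] result
#' @param grf data frame with columns `Fx_N`, `Fy_N`, `COPx_m` at the
#'   kinematic rate for the plate under the analyzed leg
#' @param side body side, `"right"` or `"left"`
#' @return data frame (class `kinetics_series`) with time, moments in Nm
#'   and Nm/kg (`ankle_moment*` plantarflexion +, `knee_moment*` and
#'   `hip_moment*` extension +), joint reaction forces in N, and `grf_bw`
#' @export
newton_euler_planar <- function(trial, model, grf,
                                side = c("right", "left")) {
  side <- match.arg(side)
  pre <- if (side == "right") "R" else "L"
  rate <- trial$rate_kin
  n <- n_frames(trial)
  if (nrow(grf) != n)
    stop("GRF series length (", nrow(grf), ") does not match the number of ",
         "kinematic frames (", n, "); decimate with downsample_force_to_kin()")
  M <- model$subject$mass
  g <- GRAVITY

  hip <- marker_xy(trial, paste0(pre, "HIP"))
  kne <- marker_xy(trial, paste0(pre, "KNE"))
  ank <- marker_xy(trial, paste0(pre, "ANK"))
  hee <- marker_xy(trial, paste0(pre, "HEE"))
  toe <- marker_xy(trial, paste0(pre, "TOE"))

  sf <- model_segment(model, "foot")
  ss <- model_segment(model, "shank")
  st <- model_segment(model, "thigh")

  foot  <- segment_kinematics(hee, toe, sf$com_fraction, rate)
  shank <- segment_kinematics(kne, ank, ss$com_fraction, rate)
  thigh <- segment_kinematics(hip, kne, st$com_fraction, rate)

  Fgx <- grf$Fx_N; Fgy <- grf$Fy_N
  cop <- cbind(grf$COPx_m, 0)

  loaded <- Fgy > 20
  if (any(loaded)) {
    lo <- pmin(hee[loaded, 1], toe[loaded, 1]) - 0.10
    hi <- pmax(hee[loaded, 1], toe[loaded, 1]) + 0.10
    if (any(cop[loaded, 1] < lo | cop[loaded, 1] > hi))
      warning("COP falls more than 10 cm outside the foot during contact")
  }

  # foot: distal load = GRF at the COP
  Fax <- sf$mass * foot$acc[, 1] - Fgx
  Fay <- sf$mass * foot$acc[, 2] + sf$mass * g - Fgy
  Ma <- sf$inertia * foot$alpha -
    cross_z(cop[, 1] - foot$com[, 1], cop[, 2] - foot$com[, 2], Fgx, Fgy) -
    cross_z(ank[, 1] - foot$com[, 1], ank[, 2] - foot$com[, 2], Fax, Fay)

  # shank: distal load = reaction to the ankle load
  Fkx <- ss$mass * shank$acc[, 1] + Fax
  Fky <- ss$mass * shank$acc[, 2] + ss$mass * g + Fay
  Mk <- ss$inertia * shank$alpha + Ma -
    cross_z(ank[, 1] - shank$com[, 1], ank[, 2] - shank$com[, 2], -Fax, -Fay) -
    cross_z(kne[, 1] - shank$com[, 1], kne[, 2] - shank$com[, 2], Fkx, Fky)

  # thigh: distal load = reaction to the knee load
  Fhx <- st$mass * thigh$acc[, 1] + Fkx
  Fhy <- st$mass * thigh$acc[, 2] + st$mass * g + Fky
  Mh <- st$inertia * thigh$alpha + Mk -
    cross_z(kne[, 1] - thigh$com[, 1], kne[, 2] - thigh$com[, 2], -Fkx, -Fky) -
    cross_z(hip[, 1] - thigh$com[, 1], hip[, 2] - thigh$com[, 2], Fhx, Fhy)

  out <- data.frame(
    time = (seq_len(n) - 1) / rate,
    ankle_moment_nm = -Ma,       # plantarflexion positive
    knee_moment_nm = Mk,         # extension positive
    hip_moment_nm = -Mh,         # extension positive
    ankle_reaction_x = Fax, ankle_reaction_y = Fay,
    knee_reaction_x = Fkx, knee_reaction_y = Fky,
    hip_reaction_x = Fhx, hip_reaction_y = Fhy,
    grf_bw = Fgy / (M * g)
  )
  out$ankle_moment_nmkg <- out$ankle_moment_nm / M
  out$knee_moment_nmkg <- out$knee_moment_nm / M
  out$hip_moment_nmkg <- out$hip_moment_nm / M
  class(out) <- c("kinetics_series", class(out))
  out
}

#' Joint powers from moments and angular velocities
#'
#' `P = M * omega` per frame with both factors in the shared clinical
#' conventions (extension / plantarflexion positive), so that concentric
#' work is positive and eccentric absorption negative. Adds `*_power_w`
#' and `*_power_wkg` columns.
#'
#' @param kinetics a [newton_euler_planar()] result
#' @param velocities an [angular_velocity()] result (anatomical angle
#'   rates, deg/s)
#' @param mass subject mass, kg (for the normalized columns)
#' @return `kinetics` with power columns added
#' @export
joint_power <- function(kinetics, velocities, mass) {
  if (nrow(kinetics) != nrow(velocities))
    stop("kinetics and velocity series have different lengths")
  # conventional angular velocities: extension (hip, knee) and
  # plantarflexion (ankle) positive, rad/s
  w_ankle <- -velocities$ankle * DEG2RAD
  w_knee <- -velocities$knee * DEG2RAD
  w_hip <- -velocities$hip * DEG2RAD
  kinetics$ankle_power_w <- kinetics$ankle_moment_nm * w_ankle
  kinetics$knee_power_w <- kinetics$knee_moment_nm * w_knee
  kinetics$hip_power_w <- kinetics$hip_moment_nm * w_hip
  kinetics$ankle_power_wkg <- kinetics$ankle_power_w / mass
  kinetics$knee_power_wkg <- kinetics$knee_power_w / mass
  kinetics$hip_power_wkg <- kinetics$hip_power_w / mass
  kinetics
}
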
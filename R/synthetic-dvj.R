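# Synthetic drop-vertical-jump generator.
#
# Builds dynamically self-consistent trials: joint-angle trajectories are
# piecewise quintic (C2 everywhere), marker positions follow by forward
# kinematics of the planar chain, the whole-body CoM follows from the
# markers plus anthropometric masses, and the vertical ground reaction
# force is derived from the CoM acceleration (F = m (g + a)). Because the
# force is derived from the generated motion, impulse-momentum consistency
# holds by construction.
#
# Timeline of a trial:
#   hold      standing on the platform, approach pose, drop height above
#   free fall rigid-body fall (GRF = 0)
#   touchdown short C2 transition in which the foot decelerates and the
#             joints begin to flex, reaching the prescribed initial-contact
#             angles (with nonzero angular velocity) exactly at contact
#   landing   initial contact to peak flexion (prescribed duration)
#   propulsion peak flexion to take-off (prescribed duration)
#   flight    ballistic rise; pelvis apex = standing height + jump height

run_with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Default take-off configuration and joint angular-velocity direction at
# take-off (deg, deg/s). The pose is deliberately flexed: with an
# ankle-rooted flat-foot chain (no heel rise) the pelvis can only leave the
# ground fast if the knee still has extension range at take-off.
TAKEOFF_POSE <- function(params) {
  c(pelvis = params$pelvic_tilt_ic, hip = 25, knee = 45, ankle = 5)
}
TAKEOFF_VELOCITY_PATTERN <- c(pelvis = 0, hip = -100, knee = -700, ankle = -200)

# Joint angular velocity at initial contact, as per-joint multiples of the
# mean landing-phase rate. Above 1, a joint's landing quintic decays from
# touchdown toward the peak-flexion rest point, so the CoM decelerates
# through absorption (positive GRF) — the morphology of a real landing.
# The hip carries a larger share and the knee a smaller one: their
# difference drives the shank rotation rate, and a quiet shank at impact
# keeps the CoM deceleration demand (and with it the angular-acceleration
# content near the filter cutoff) low. Factors above ~2.8 would make the
# quintic overshoot its end point; all stay well below.
IC_VELOCITY_FACTOR <- c(pelvis = 2, hip = 2.5, knee = 1.6, ankle = 1.6)

# Joints whose angular acceleration is shaped at initial contact to control
# the CoM deceleration; the ankle and pelvis barely move the CoM (near-zero
# Jacobian) and are left unshaped so their trajectories stay maximally
# band-limited.
IC_SHAPE_WEIGHTS <- c(pelvis = 0, hip = 1, knee = 1, ankle = 0)

# Angular acceleration at peak flexion for the largest-excursion joint
# (deg/s^2, negative = definite reversal), scaled per joint by excursion.
# A flat (zero-curvature) peak would let the analysis filter's residual
# ripple wander the detected peak instant by several frames; a definite
# reversal, as in real landings, localizes it.
PEAK_REVERSAL_CURVATURE <- -2000

JOINTS <- c("pelvis", "hip", "knee", "ankle")

eval_joint_polys <- function(coefs_list, t, deriv = 0) {
  out <- sapply(JOINTS, function(j) poly_eval(coefs_list[[j]], t, deriv))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(t),
                                       dimnames = list(NULL, JOINTS))
  out
}

#' Generate a synthetic drop-vertical-jump trial
#'
#' Produces a [trial_recording()] with planar marker trajectories at the
#' kinematic rate and two force-plate channel sets (vertical and
#' anterior-posterior force, centre of pressure) at the force rate, for a
#' bilateral DVJ realizing the prescription in `params`: drop from the
#' platform, touchdown at the prescribed initial-contact angles, absorption
#' to the prescribed peak angles over the landing duration, propulsion to
#' take-off, and ballistic flight whose pelvis apex exceeds standing height
#' by the prescribed jump height. Ground reaction force is split equally
#' between the two plates (bilateral symmetric task).
#'
#' The returned object carries a `truth` attribute with the noise-free
#' prescription as realized: event times, noise-free joint-angle series,
#' the contact-phase CoM path and total vertical GRF.
#'
#' @param subject a [subject_spec()]
#' @param params a [condition_params()] (see [preset()])
#' @param rate_kin kinematic sampling rate, Hz
#' @param rate_force force sampling rate, Hz (integer multiple of `rate_kin`)
#' @param tau_touchdown duration of the root (foot) touchdown transition, s
#' @param tau_preshape duration of the pre-contact joint-angle preparation
#'   (legs pre-shaping during the fall), s; kept long so the angle
#'   trajectories stay band-limited well below the 15 Hz analysis cutoff
#' @return a `trial_recording`
#' @examples
#' trial <- generate_dvj_trial(subject_spec(), preset("baseline"))
#' @export
generate_dvj_trial <- function(subject, params, rate_kin = 200,
                               rate_force = 1000, tau_touchdown = 0.06,
                               tau_preshape = 0.25) {
  stopifnot(inherits(subject, "subject_spec"),
            inherits(params, "condition_params"))
  if (rate_force %% rate_kin != 0)
    stop("rate_force must be an integer multiple of rate_kin")
  model <- build_body_model(subject)
  M <- subject$mass
  h_a <- subject$segment_lengths$ankle_height
  T_L <- params$landing_duration / 1000
  T_P <- params$propulsion_duration / 1000
  T_c <- T_L + T_P
  H_jump <- params$jump_height / 100
  tau <- tau_touchdown

  theta_ic <- c(pelvis = params$pelvic_tilt_ic, hip = params$hip_flexion_ic,
                knee = params$knee_flexion_ic, ankle = params$ankle_ic)
  theta_pk <- c(pelvis = params$peak_pelvic_tilt, hip = params$peak_hip_flexion,
                knee = params$peak_knee_flexion, ankle = params$peak_ankle)
  omega_ic <- IC_VELOCITY_FACTOR * (theta_pk - theta_ic) / T_L
  excursion <- theta_pk - theta_ic
  alpha_pk <- PEAK_REVERSAL_CURVATURE * excursion / max(abs(excursion))

  # --- landing splines: (IC angle, IC velocity) -> (peak, reversal) -------
  make_landing <- function(alpha_ic) {
    out <- lapply(JOINTS, function(j)
      quintic_coefs(theta_ic[j], omega_ic[j], alpha_ic[j], theta_pk[j],
                    0, alpha_pk[j], T_L))
    names(out) <- JOINTS
    out
  }
  alpha_ic <- setNames(rep(0, 4), JOINTS)
  landing <- make_landing(alpha_ic)

  # --- take-off state: pose, joint velocities scaled so the pelvis leaves
  #     the ground at the ballistic speed the jump height requires ---------
  theta_to <- TAKEOFF_POSE(params)
  y_pelvis_static <- pelvis_height_at_pose(0, 0, 0, 0, c(0, h_a), subject)
  pelv_y <- function(th) pelvis_height_at_pose(th[1], th[2], th[3], th[4],
                                               c(0, h_a), subject)
  pelv_x <- function(th) {
    mk <- fk_markers(list(pelvis = th[1], hip = th[2], knee = th[3],
                          ankle = th[4]), matrix(c(0, h_a), 1, 2), subject)
    mk$pelvis_centroid[1, 1]
  }
  y_to <- pelv_y(theta_to)
  apex_gap <- y_pelvis_static + H_jump - y_to
  if (apex_gap <= 0)
    stop("infeasible params: jump height is not reachable from the ",
         "take-off configuration")
  v_to <- sqrt(2 * GRAVITY * apex_gap)
  d_dir <- TAKEOFF_VELOCITY_PATTERN
  J_pelv_y <- pose_jacobian(pelv_y, theta_to)   # m per degree
  denom <- sum(J_pelv_y * d_dir)
  if (denom <= 0)
    stop("infeasible params: take-off velocity pattern does not raise the pelvis")
  lambda <- v_to / denom
  omega_to <- lambda * d_dir
  vx_to <- sum(pose_jacobian(pelv_x, theta_to) * omega_to)

  make_propulsion <- function(alpha_to) {
    out <- lapply(JOINTS, function(j)
      quintic_coefs(theta_pk[j], 0, alpha_pk[j], theta_to[j], omega_to[j],
                    alpha_to[j], T_P))
    names(out) <- JOINTS
    out
  }
  propulsion <- make_propulsion(setNames(rep(0, 4), JOINTS))

  # contact-phase angles, extended smoothly beyond both contact boundaries
  contact_angles <- function(t_rel, deriv = 0) {
    th <- matrix(NA_real_, length(t_rel), 4, dimnames = list(NULL, JOINTS))
    in_land <- t_rel <= T_L
    if (any(in_land))
      th[in_land, ] <- eval_joint_polys(landing, t_rel[in_land], deriv)
    if (any(!in_land))
      th[!in_land, ] <- eval_joint_polys(propulsion, t_rel[!in_land] - T_L,
                                         deriv)
    th
  }
  com_contact <- function(t_rel) {
    th <- contact_angles(t_rel)
    mk <- fk_markers(as.data.frame(th), cbind(0, rep(h_a, length(t_rel))),
                     subject)
    whole_body_com(mk, model)
  }

  com_y_accel_at <- function(t_rel) {
    hstep <- 5e-4
    (com_contact(t_rel + hstep)[, 2] - 2 * com_contact(t_rel)[, 2] +
       com_contact(t_rel - hstep)[, 2]) / hstep^2
  }
  com_y_jac <- function(pose) {
    pose_jacobian(function(th) com_at_pose(th[1], th[2], th[3], th[4],
                                           c(0, h_a), model)[2], pose)
  }

  # shape the initial-contact angular accelerations (hip and knee) so the
  # CoM deceleration is zero right at touchdown and positive after (the
  # joint-space Jacobian grows with flexion, so unshaped splines would
  # briefly accelerate the CoM downward and imply negative GRF at impact)
  a_ic_target <- 0
  shaped <- IC_SHAPE_WEIGHTS * omega_ic
  nu <- (a_ic_target - com_y_accel_at(0)) / sum(com_y_jac(theta_ic) * shaped)
  alpha_ic <- nu * shaped
  landing <- make_landing(alpha_ic)

  # shape the take-off acceleration so the implied GRF lands near zero at
  # take-off (F(t_to-) ~ 30 N) instead of a large step
  a_target <- -GRAVITY + 30 / M
  mu <- (a_target - com_y_accel_at(T_c)) / sum(com_y_jac(theta_to) * d_dir)
  propulsion <- make_propulsion(mu * d_dir)

  # --- pre-contact joint preparation and root touchdown -------------------
  tau_ang <- tau_preshape
  theta_appr <- theta_ic - omega_ic * tau_ang / 2
  transition <- lapply(JOINTS, function(j)
    quintic_coefs(theta_appr[j], 0, 0, theta_ic[j], omega_ic[j],
                  alpha_ic[j], tau_ang))
  names(transition) <- JOINTS
  # ankle root decelerates to rest exactly at contact; fall speed and
  # transition displacement solved jointly so total descent = drop height
  y1 <- 0
  for (i in 1:8) {
    v1 <- sqrt(2 * GRAVITY * max(params$drop_height - y1, 1e-9))
    y1 <- v1 * tau / 2
  }
  root_trans <- quintic_coefs(h_a + y1, -v1, -GRAVITY, h_a, 0, 0, tau)
  t_fall <- v1 / GRAVITY

  # --- timeline, snapped so initial contact falls on a kinematic frame ----
  pre_raw <- 0.05 + max(t_fall + tau, tau_ang)
  t_ic <- ceiling(pre_raw * rate_kin) / rate_kin
  t_hold <- t_ic - tau - t_fall
  t_peak <- t_ic + T_L
  t_to <- t_ic + T_c
  t_end <- t_to + v_to / GRAVITY + 0.15
  n_kin <- floor(t_end * rate_kin) + 1
  t_kin <- (seq_len(n_kin) - 1) / rate_kin
  ratio <- rate_force / rate_kin
  n_force <- (n_kin - 1) * ratio + 1
  t_force <- (seq_len(n_force) - 1) / rate_force

  angles_at <- function(t) {
    th <- matrix(NA_real_, length(t), 4, dimnames = list(NULL, JOINTS))
    ph1 <- t < t_ic - tau_ang
    ph2 <- !ph1 & t < t_ic
    ph3 <- t >= t_ic & t < t_to
    ph4 <- t >= t_to
    if (any(ph1)) th[ph1, ] <- matrix(theta_appr, sum(ph1), 4, byrow = TRUE)
    if (any(ph2)) th[ph2, ] <- eval_joint_polys(transition,
                                                t[ph2] - (t_ic - tau_ang))
    if (any(ph3)) th[ph3, ] <- contact_angles(t[ph3] - t_ic)
    if (any(ph4)) th[ph4, ] <- matrix(theta_to, sum(ph4), 4, byrow = TRUE)
    th
  }
  root_y_at <- function(t) {
    y <- rep(h_a, length(t))
    y[t < t_hold] <- h_a + params$drop_height
    ff <- t >= t_hold & t < t_ic - tau
    y[ff] <- h_a + params$drop_height - GRAVITY * (t[ff] - t_hold)^2 / 2
    tr <- t >= t_ic - tau & t < t_ic
    y[tr] <- poly_eval(root_trans, t[tr] - (t_ic - tau))
    y
  }

  th_kin <- angles_at(t_kin)
  mk <- fk_markers(as.data.frame(th_kin), cbind(0, root_y_at(t_kin)), subject)
  # ballistic whole-body translation after take-off (pelvis velocity at TO)
  post <- t_kin >= t_to
  dt <- t_kin[post] - t_to
  off_x <- vx_to * dt
  off_y <- v_to * dt - GRAVITY * dt^2 / 2
  for (m in names(mk)) {
    mk[[m]][post, 1] <- mk[[m]][post, 1] + off_x
    mk[[m]][post, 2] <- mk[[m]][post, 2] + off_y
  }

  # feasibility: the generated knee trajectory must peak at the prescribed
  # value, at the prescribed instant
  grid <- seq(0, T_c, by = 1 / rate_force)
  knee_fine <- contact_angles(grid)[, "knee"]
  if (max(knee_fine) > theta_pk["knee"] + 1e-6)
    stop("infeasible params: knee trajectory overshoots the prescribed peak ",
         "flexion (landing too short for the prescribed angular velocities)")
  if (abs(max(knee_fine) - theta_pk["knee"]) > 0.01)
    stop("infeasible params: knee trajectory fails to reach the prescribed ",
         "peak flexion")

  # --- ground reaction force from the CoM path -----------------------------
  in_contact <- t_force >= t_ic & t_force < t_to
  idx_c <- which(in_contact)
  t_rel_ext <- c(t_force[idx_c], max(t_force[idx_c]) + 1 / rate_force) - t_ic
  t_rel_ext <- c(min(t_rel_ext) - 1 / rate_force, t_rel_ext)
  com_ext <- com_contact(t_rel_ext)
  nn <- nrow(com_ext)
  acc <- function(y) (y[3:nn] - 2 * y[2:(nn - 1)] + y[1:(nn - 2)]) *
    rate_force^2
  a_y <- acc(com_ext[, 2])
  a_x <- acc(com_ext[, 1])
  F_total <- rep(0, n_force)
  F_total[idx_c] <- M * (GRAVITY + a_y)
  Fx_total <- rep(0, n_force)
  Fx_total[idx_c] <- M * a_x
  neg <- F_total[idx_c] < 0
  if (any(neg)) {
    runs <- rle(neg)
    if (max(runs$lengths[runs$values]) > 0.050 * rate_force)
      stop("infeasible params: implied total vertical GRF is negative for ",
           "more than 50 ms during contact")
  }

  # centre of pressure: forefoot strike settling toward the forefoot at
  # push-off, smooth in time, held at its end values outside contact
  u <- pmin(pmax((t_force - t_ic) / T_c, 0), 1)
  copx <- 0.11 + 0.05 * smoothstep5(u)

  plate <- function() data.frame(time_s = t_force, Fx_N = Fx_total / 2,
                                 Fy_N = F_total / 2, COPx_m = copx)
  plates <- list(right = plate(), left = plate())

  markers <- planar_to_marker_set(mk, n_kin)

  # measurement noise
  if (params$marker_noise_sd > 0 || params$force_noise_sd > 0) {
    run_with_seed(params$seed, {
      if (params$marker_noise_sd > 0)
        for (m in names(markers))
          markers[[m]] <- markers[[m]] +
            matrix(rnorm(3 * n_kin, 0, params$marker_noise_sd), n_kin, 3)
      if (params$force_noise_sd > 0)
        for (pl in names(plates)) {
          plates[[pl]]$Fy_N <- plates[[pl]]$Fy_N +
            rnorm(n_force, 0, params$force_noise_sd)
          plates[[pl]]$Fx_N <- plates[[pl]]$Fx_N +
            rnorm(n_force, 0, params$force_noise_sd)
        }
    })
  }

  trial <- trial_recording(markers = markers, rate_kin = rate_kin,
                           plates = plates, rate_force = rate_force,
                           subject = subject, trial_kind = "dvj")
  attr(trial, "truth") <- list(
    t_ic = t_ic, t_peak = t_peak, t_to = t_to,
    v_to = v_to, y_pelvis_static = y_pelvis_static,
    angles = data.frame(time = t_kin, th_kin),
    com_contact = data.frame(time = t_force[idx_c],
                             x = com_ext[2:(nn - 1), 1],
                             y = com_ext[2:(nn - 1), 2]),
    F_total = F_total, params = params
  )
  trial
}

# Expand one-leg planar marker geometry into the bilateral 3D-shaped marker
# set (z mediolateral offsets; the two legs are identical in the sagittal
# plane for this bilateral task).
planar_to_marker_set <- function(mk, n) {
  z <- function(v) rep(v, n)
  list(
    RASI = cbind(mk$pelvis_ant, z(0.12)),  LASI = cbind(mk$pelvis_ant, z(-0.12)),
    RPSI = cbind(mk$pelvis_post, z(0.06)), LPSI = cbind(mk$pelvis_post, z(-0.06)),
    RHIP = cbind(mk$hip, z(0.09)),  LHIP = cbind(mk$hip, z(-0.09)),
    RKNE = cbind(mk$knee, z(0.09)), LKNE = cbind(mk$knee, z(-0.09)),
    RANK = cbind(mk$ankle, z(0.09)), LANK = cbind(mk$ankle, z(-0.09)),
    RHEE = cbind(mk$heel, z(0.09)), LHEE = cbind(mk$heel, z(-0.09)),
    RTOE = cbind(mk$toe, z(0.09)),  LTOE = cbind(mk$toe, z(-0.09))
  )
}

#' Generate a static standing reference trial
#'
#' At least one second of markers in the anatomical standing pose (all joint
#' angles at neutral) with the total vertical ground reaction force equal to
#' body weight, split evenly between the two plates.
#'
#' @param subject a [subject_spec()]
#' @param duration trial length in s
#' @param marker_noise_sd,force_noise_sd measurement noise SDs (m, N)
#' @param seed noise seed
#' @param rate_kin,rate_force sampling rates, Hz
#' @return a `trial_recording` of kind `"static"`
#' @export
generate_static_trial <- function(subject, duration = 1.2,
                                  marker_noise_sd = 5e-4, force_noise_sd = 2,
                                  seed = 1L, rate_kin = 200,
                                  rate_force = 1000) {
  stopifnot(inherits(subject, "subject_spec"))
  if (duration < 1) stop("static trial must be at least 1 s long")
  model <- build_body_model(subject)
  h_a <- subject$segment_lengths$ankle_height
  n_kin <- floor(duration * rate_kin) + 1
  ratio <- rate_force / rate_kin
  n_force <- (n_kin - 1) * ratio + 1
  t_force <- (seq_len(n_force) - 1) / rate_force

  zero <- rep(0, n_kin)
  mk <- fk_markers(list(pelvis = zero, hip = zero, knee = zero, ankle = zero),
                   cbind(0, rep(h_a, n_kin)), subject)
  markers <- planar_to_marker_set(mk, n_kin)
  com_x <- whole_body_com(lapply(mk, function(m) m[1, , drop = FALSE]),
                          model)[1, 1]
  plate <- function() data.frame(
    time_s = t_force, Fx_N = rep(0, n_force),
    Fy_N = rep(subject$mass * GRAVITY / 2, n_force),
    COPx_m = rep(com_x, n_force)
  )
  plates <- list(right = plate(), left = plate())

  if (marker_noise_sd > 0 || force_noise_sd > 0) {
    run_with_seed(seed, {
      if (marker_noise_sd > 0)
        for (m in names(markers))
          markers[[m]] <- markers[[m]] +
            matrix(rnorm(3 * n_kin, 0, marker_noise_sd), n_kin, 3)
      if (force_noise_sd > 0)
        for (pl in names(plates)) {
          plates[[pl]]$Fy_N <- plates[[pl]]$Fy_N + rnorm(n_force, 0, force_noise_sd)
          plates[[pl]]$Fx_N <- plates[[pl]]$Fx_N + rnorm(n_force, 0, force_noise_sd)
        }
    })
  }
  trial_recording(markers = markers, rate_kin = rate_kin, plates = plates,
                  rate_force = rate_force, subject = subject,
                  trial_kind = "static")
}

#' Parameters for the synthetic muscle-damage indicator panel
#'
#' @param panel data frame with columns `indicator`, `timepoint`, `mean`,
#'   `sd` (defaults to [eimd_reference_panel()])
#' @param n_subjects number of subjects (>= 2)
#' @param correlation within-subject correlation across timepoints, induced
#'   by a shared subject random effect (0..1)
#' @param seed sampling seed
#' @return an object of class `eimd_panel_params`
#' @export
eimd_panel_params <- function(panel = eimd_reference_panel(),
                              n_subjects = 13, correlation = 0.5,
                              seed = 1L) {
  stopifnot(is.data.frame(panel),
            all(c("indicator", "timepoint", "mean", "sd") %in% names(panel)))
  if (any(panel$sd < 0)) stop("indicator SDs must be >= 0")
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (correlation < 0 || correlation > 1)
    stop("correlation must be in [0, 1]")
  structure(list(panel = panel, n_subjects = as.integer(n_subjects),
                 correlation = correlation, seed = as.integer(seed)),
            class = "eimd_panel_params")
}

#' Generate a synthetic muscle-damage indicator panel
#'
#' Samples per-subject, per-timepoint indicator values from normal
#' distributions with the configured means and SDs; values within a subject
#' are correlated across timepoints through a shared subject random effect.
#' Soreness (`DOMS`) is clipped to the 0-10 scale and creatine kinase
#' (`CK`) at zero after sampling. Deterministic given the seed.
#'
#' @param params an [eimd_panel_params()]
#' @return data frame with columns `subject`, `indicator`, `timepoint`,
#'   `value`
#' @examples
#' head(generate_eimd_panel(eimd_panel_params(seed = 7)))
#' @export
generate_eimd_panel <- function(params) {
  stopifnot(inherits(params, "eimd_panel_params"))
  panel <- params$panel
  n <- params$n_subjects
  rho <- params$correlation
  run_with_seed(params$seed, {
    out <- do.call(rbind, lapply(unique(panel$indicator), function(ind) {
      sub <- panel[panel$indicator == ind, , drop = FALSE]
      b <- rnorm(n)                       # shared subject effect
      do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
        e <- rnorm(n)
        v <- sub$mean[i] + sub$sd[i] * (sqrt(rho) * b + sqrt(1 - rho) * e)
        if (ind == "DOMS") v <- pmin(pmax(v, 0), 10)
        if (ind == "CK") v <- pmax(v, 0)
        data.frame(subject = seq_len(n), indicator = ind,
                   timepoint = sub$timepoint[i], value = v,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(out) <- NULL
    out
  })
}
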
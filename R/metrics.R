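# Phase segmentation and extraction of the trial-level outcome set:
# per-phase peaks, knee joint stiffness, phase durations and jump height.

#' Split the contact into landing and propulsion phases
#'
#' The landing phase runs from initial contact to the instant of peak knee
#' flexion, the propulsion phase from peak knee flexion to take-off. The
#' peak is the global maximum of knee flexion within the contact, earliest
#' frame on ties.
#'
#' @param events a [detect_events()] result
#' @param knee_angle knee flexion series (deg) at the kinematic rate,
#'   covering the contact
#' @return `events` extended with `idx_peak_kin` and `t_peak`; landing is
#'   `[idx_ic_kin, idx_peak_kin]`, propulsion `(idx_peak_kin,
#'   idx_takeoff_kin)`
#' @export
split_phases <- function(events, knee_angle) {
  i0 <- events$idx_ic_kin
  i1 <- min(events$idx_takeoff_kin - 1L, length(knee_angle))
  if (i1 <= i0) stop("contact interval does not cover any kinematic frame")
  w <- knee_angle[i0:i1]
  idx_peak <- i0 + which.max(w) - 1L
  if (idx_peak == i0 || idx_peak == i1)
    warning("peak knee flexion at a contact boundary (degenerate landing)")
  events$idx_peak_kin <- idx_peak
  events$t_peak <- (idx_peak - 1) / events$rate_kin
  events
}

#' Knee joint stiffness over the landing phase
#'
#' Ratio of the knee moment change to the knee angular excursion between
#' initial contact and the instant of peak knee flexion, with both series
#' sampled at those two instants (Nm/kg per degree). `mode = "peak_ratio"`
#' instead uses the landing-phase extrema of moment and angle.
#'
#' @param knee_moment knee extension moment series, Nm/kg, kinematic rate
#' @param knee_angle knee flexion series, deg
#' @param events events with `idx_peak_kin` (see [split_phases()])
#' @param mode `"instants"` (default) or `"peak_ratio"`
#' @return stiffness in Nm/kg/deg
#' @export
knee_stiffness <- function(knee_moment, knee_angle, events,
                           mode = c("instants", "peak_ratio")) {
  mode <- match.arg(mode)
  i0 <- events$idx_ic_kin
  ip <- events$idx_peak_kin
  if (is.null(ip)) stop("events lack the peak-knee-flexion index; ",
                        "run split_phases() first")
  if (mode == "instants") {
    d_m <- knee_moment[ip] - knee_moment[i0]
    d_a <- knee_angle[ip] - knee_angle[i0]
  } else {
    w <- i0:ip
    d_m <- max(knee_moment[w]) - min(knee_moment[w])
    d_a <- max(knee_angle[w]) - min(knee_angle[w])
  }
  if (abs(d_a) < 1e-9)
    stop("knee joint stiffness undefined: zero knee range of motion ",
         "over the landing phase")
  d_m / d_a
}

#' Extract the trial outcome set
#'
#' All per-trial outcome variables: per-phase GRF peaks (BW multiples),
#' angles at initial contact and their landing-phase peaks (deg), peak
#' landing moments (Nm/kg), peak landing power absorption and propulsion
#' power generation (W/kg), knee joint stiffness, phase durations (ms;
#' landing and propulsion bounded by the kinematic-rate peak-flexion
#' frame, total contact at force-rate resolution) and jump height (cm).
#'
#' @param trial the raw `trial_recording` (used for timing metadata)
#' @param angles [joint_angles()] result
#' @param kinetics [newton_euler_planar()] + [joint_power()] result
#' @param events [split_phases()] result
#' @param static_trial the subject's static trial (for jump height)
#' @param stiffness_mode see [knee_stiffness()]
#' @return one-row data frame of class `dvj_metrics`
#' @export
extract_metrics <- function(trial, angles, kinetics, events, static_trial,
                            stiffness_mode = "instants") {
  i0 <- events$idx_ic_kin
  ip <- events$idx_peak_kin
  i1 <- events$idx_takeoff_kin
  if (is.null(ip)) stop("events lack the peak-knee-flexion index")
  landing <- i0:ip
  propulsion <- if (ip + 1 <= i1 - 1) (ip + 1):(i1 - 1) else integer(0)
  if (length(propulsion) == 0) propulsion <- ip

  t_peak <- (ip - 1) / trial$rate_kin
  landing_ms <- (t_peak - events$t_ic) * 1000
  propulsion_ms <- (events$t_takeoff - t_peak) * 1000

  peak <- function(x, w) max(x[w])
  trough <- function(x, w) min(x[w])

  out <- data.frame(
    grf_peak_landing_bw = peak(kinetics$grf_bw, landing),
    grf_peak_propulsion_bw = peak(kinetics$grf_bw, propulsion),
    pelvis_tilt_ic_deg = angles$pelvis[i0],
    pelvis_tilt_peak_landing_deg = peak(angles$pelvis, landing),
    hip_flexion_ic_deg = angles$hip[i0],
    hip_flexion_peak_landing_deg = peak(angles$hip, landing),
    hip_moment_peak_landing_nmkg = peak(kinetics$hip_moment_nmkg, landing),
    hip_power_absorption_landing_wkg = trough(kinetics$hip_power_wkg, landing),
    hip_power_generation_propulsion_wkg = peak(kinetics$hip_power_wkg, propulsion),
    knee_flexion_ic_deg = angles$knee[i0],
    knee_flexion_peak_landing_deg = peak(angles$knee, landing),
    knee_moment_peak_landing_nmkg = peak(kinetics$knee_moment_nmkg, landing),
    knee_power_absorption_landing_wkg = trough(kinetics$knee_power_wkg, landing),
    knee_power_generation_propulsion_wkg = peak(kinetics$knee_power_wkg, propulsion),
    ankle_angle_ic_deg = angles$ankle[i0],
    ankle_angle_peak_landing_deg = peak(angles$ankle, landing),
    ankle_moment_peak_landing_nmkg = peak(kinetics$ankle_moment_nmkg, landing),
    ankle_power_absorption_landing_wkg = trough(kinetics$ankle_power_wkg, landing),
    ankle_power_generation_propulsion_wkg = peak(kinetics$ankle_power_wkg, propulsion),
    knee_stiffness_nmkg_deg = knee_stiffness(kinetics$knee_moment_nmkg,
                                             angles$knee, events,
                                             mode = stiffness_mode),
    contact_duration_ms = (events$t_takeoff - events$t_ic) * 1000,
    landing_duration_ms = landing_ms,
    propulsion_duration_ms = propulsion_ms,
    jump_height_cm = jump_height(trial, static_trial, events)
  )
  class(out) <- c("dvj_metrics", class(out))
  out
}

#' Average trial metrics
#'
#' Field-wise arithmetic mean over the trials of one subject and session.
#'
#' @param metrics_list list of [extract_metrics()] rows
#' @return one-row `dvj_metrics` data frame
#' @export
average_trials <- function(metrics_list) {
  if (length(metrics_list) == 0) stop("no trial metrics to average")
  all <- do.call(rbind, metrics_list)
  out <- as.data.frame(as.list(colMeans(all)))
  class(out) <- c("dvj_metrics", class(out))
  out
}

#' Run the full single-trial analysis pipeline
#'
#' Event detection on the raw force, zero-lag filtering of markers and
#' forces, joint kinematics, planar inverse dynamics of the dominant leg,
#' phase segmentation and metric extraction.
#'
#' @param trial a raw DVJ `trial_recording`
#' @param static_trial the subject's static `trial_recording`
#' @param config a [dvj_config()] list
#' @return list with `events`, `angles`, `velocities`, `kinetics` and
#'   `metrics`
#' @examples
#' \donttest{
#' subj <- subject_spec()
#' trial <- generate_dvj_trial(subj, preset("baseline"))
#' static <- generate_static_trial(subj)
#' res <- analyze_trial(trial, static)
#' res$metrics$knee_flexion_peak_landing_deg
#' }
#' @export
analyze_trial <- function(trial, static_trial, config = dvj_config()) {
  validate_config(config)
  events <- detect_events(trial, threshold = config$threshold,
                          debounce = config$debounce,
                          min_contact = config$min_contact)
  side <- config$dominant_side
  model <- build_body_model(trial$subject, table = config$anthropometric_table)

  filt <- filter_trial(trial, cutoff = config$cutoff,
                       order = config$filter_order,
                       order_interpretation = config$order_interpretation)
  static_filt <- filter_trial(static_trial, cutoff = config$cutoff,
                              order = config$filter_order,
                              order_interpretation = config$order_interpretation)
  offset <- ankle_neutral_offset(static_filt, side = side)
  angles <- joint_angles(filt, side = side, ankle_offset = offset)
  velocities <- angular_velocity(angles, filt$rate_kin)

  plate_raw <- trial$plates[[side]]
  if (is.null(plate_raw))
    stop("no force plate assigned to the ", side, " leg")
  grf_kin <- data.frame(
    Fx_N = downsample_force_to_kin(plate_raw$Fx_N, trial$rate_force,
                                   trial$rate_kin, cutoff = config$cutoff,
                                   order = config$filter_order),
    Fy_N = downsample_force_to_kin(plate_raw$Fy_N, trial$rate_force,
                                   trial$rate_kin, cutoff = config$cutoff,
                                   order = config$filter_order),
    COPx_m = plate_raw$COPx_m[seq(1, nrow(plate_raw),
                                  by = trial$rate_force / trial$rate_kin)]
  )
  kinetics <- newton_euler_planar(filt, model, grf_kin, side = side)
  kinetics <- joint_power(kinetics, velocities, trial$subject$mass)

  events <- split_phases(events, angles$knee)
  metrics <- extract_metrics(filt, angles, kinetics, events,
                             filter_trial(static_trial,
                                          cutoff = config$cutoff,
                                          order = config$filter_order),
                             stiffness_mode = config$stiffness_mode)
  list(events = events, angles = angles, velocities = velocities,
       kinetics = kinetics, metrics = metrics)
}
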
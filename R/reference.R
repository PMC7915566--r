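# Published group-level reference values for the two capture sessions
# (pre-exercise baseline and 48 h after eccentric exercise-induced muscle
# damage of the knee extensors). These tables parameterize the synthetic
# generator presets and the cohort simulations.

#' Reference DVJ biomechanical measures (group means and SDs)
#'
#' The full variable set reported for the drop-vertical-jump task in the
#' muscle-damage study the package emulates: one row per variable, group
#' mean and SD for the baseline (`0h`) and 48-h post-exercise (`48h`)
#' sessions, and whether the pre/post difference was reported significant.
#' Vertical GRF is in multiples of body weight per force plate (per leg),
#' moments in Nm/kg, powers in W/kg (absorption negative), angles in
#' degrees, durations in ms, jump height in cm.
#'
#' @return data frame with columns `variable`, `label`, `mean_0h`, `sd_0h`,
#'   `mean_48h`, `sd_48h`, `significant`
#' @export
dvj_reference_measures <- function() {
  rows <- list(
    c("grf_peak_landing_bw", "Peak vertical GRF, landing (BW)", 2.04, 0.37, 1.79, 0.33, TRUE),
    c("grf_peak_propulsion_bw", "Peak vertical GRF, propulsion (BW)", 1.89, 0.32, 1.58, 0.25, TRUE),
    c("pelvis_tilt_ic_deg", "Pelvic anterior tilt at IC (deg)", 17.31, 4.4, 20.19, 7.8, FALSE),
    c("pelvis_tilt_peak_landing_deg", "Peak anterior pelvic tilt, landing (deg)", 19.74, 5.9, 25.16, 6.9, TRUE),
    c("hip_flexion_ic_deg", "Hip flexion at IC (deg)", 43.39, 6.4, 44.49, 7.5, FALSE),
    c("hip_flexion_peak_landing_deg", "Peak hip flexion, landing (deg)", 61.18, 10.5, 69.38, 10.3, TRUE),
    c("hip_moment_peak_landing_nmkg", "Peak hip extension moment, landing (Nm/kg)", 2.46, 0.69, 2.41, 0.51, FALSE),
    c("hip_power_absorption_landing_wkg", "Peak hip power absorption, landing (W/kg)", -10.8, 5.5, -10.4, 4.2, FALSE),
    c("hip_power_generation_propulsion_wkg", "Peak hip power generation, propulsion (W/kg)", 5.6, 1.8, 6.4, 1.7, FALSE),
    c("knee_flexion_ic_deg", "Knee flexion at IC (deg)", 41.61, 5.9, 40.37, 7.4, FALSE),
    c("knee_flexion_peak_landing_deg", "Peak knee flexion, landing (deg)", 84.15, 6.2, 88.66, 6.9, TRUE),
    c("knee_moment_peak_landing_nmkg", "Peak knee extension moment, landing (Nm/kg)", 3.02, 0.44, 2.53, 0.53, TRUE),
    c("knee_power_absorption_landing_wkg", "Peak knee power absorption, landing (W/kg)", -20.65, 3.9, -17.06, 4.2, TRUE),
    c("knee_power_generation_propulsion_wkg", "Peak knee power generation, propulsion (W/kg)", 18.19, 2.9, 14.76, 3.9, TRUE),
    c("ankle_angle_ic_deg", "Ankle angle at IC (deg)", -4.07, 8.6, -9.02, 6.7, FALSE),
    c("ankle_angle_peak_landing_deg", "Peak ankle angle, landing (deg)", 37.69, 4.2, 35.51, 3.1, FALSE),
    c("ankle_moment_peak_landing_nmkg", "Peak ankle moment, landing (Nm/kg)", 2.20, 0.64, 1.97, 0.35, FALSE),
    c("ankle_power_absorption_landing_wkg", "Peak ankle power absorption, landing (W/kg)", -12.93, 4.3, -11.66, 3.2, FALSE),
    c("ankle_power_generation_propulsion_wkg", "Peak ankle power generation, propulsion (W/kg)", 17.38, 3.0, 13.62, 2.7, TRUE),
    c("knee_stiffness_nmkg_deg", "Knee joint stiffness (Nm/kg/deg)", 0.077, 0.03, 0.055, 0.02, TRUE),
    c("contact_duration_ms", "Total contact phase duration (ms)", 313.2, 60.7, 381.7, 76.6, TRUE),
    c("landing_duration_ms", "Landing phase duration (ms)", 134.4, 35.4, 173.3, 44.1, TRUE),
    c("propulsion_duration_ms", "Propulsion phase duration (ms)", 178.8, 28.1, 208.4, 35.7, TRUE),
    c("jump_height_cm", "Jump height (cm)", 33.38, 1.21, 32.15, 1.4, TRUE)
  )
  out <- data.frame(
    variable = vapply(rows, `[`, character(1), 1),
    label = vapply(rows, `[`, character(1), 2),
    mean_0h = as.numeric(vapply(rows, `[`, character(1), 3)),
    sd_0h = as.numeric(vapply(rows, `[`, character(1), 4)),
    mean_48h = as.numeric(vapply(rows, `[`, character(1), 5)),
    sd_48h = as.numeric(vapply(rows, `[`, character(1), 6)),
    significant = as.logical(vapply(rows, `[`, character(1), 7)),
    stringsAsFactors = FALSE
  )
  out
}

#' Reference muscle-damage indicator panel (group means and SDs)
#'
#' Per-timepoint group mean and SD for the three muscle-damage indicators:
#' isometric peak torque of the knee extensors as a percentage of the
#' pre-exercise value (`IPT_pct`), serum creatine kinase (`CK`, U/L) and
#' delayed-onset muscle soreness on the 0-10 palpation scale (`DOMS`).
#'
#' @return data frame with columns `indicator`, `timepoint`, `mean`, `sd`
#' @export
eimd_reference_panel <- function() {
  data.frame(
    indicator = c("IPT_pct", "IPT_pct", "IPT_pct", "IPT_pct",
                  "CK", "CK", "DOMS", "DOMS", "DOMS"),
    timepoint = c("0h", "post", "24h", "48h", "0h", "48h", "0h", "24h", "48h"),
    mean = c(100, 75.4, 79.7, 80.5, 202, 2040, 0, 5.5, 6.7),
    sd   = c(0, 7.0, 10.6, 9.9, 125, 1306, 0, 1.3, 1.6),
    stringsAsFactors = FALSE
  )
}

#' Condition preset for the synthetic DVJ generator
#'
#' Returns the full parameter set (`condition_params`) for one capture
#' session: the session's group-mean joint angles at initial contact and at
#' their landing-phase peaks, phase durations, jump height, drop height and
#' measurement-noise magnitudes. `"baseline"` is the pre-exercise session,
#' `"damaged48h"` the session 48 h after eccentric exercise.
#'
#' @param name `"baseline"` or `"damaged48h"`
#' @param seed integer seed stored in the parameter set (used by
#'   [generate_dvj_trial()] for measurement noise)
#' @param marker_noise_sd optical marker noise SD in m (default 0.5 mm)
#' @param force_noise_sd force-plate noise SD in N (default 2 N)
#' @return an object of class `condition_params`
#' @examples
#' preset("baseline")$peak_knee_flexion
#' @export
preset <- function(name, seed = 1L, marker_noise_sd = 5e-4,
                   force_noise_sd = 2) {
  valid <- c("baseline", "damaged48h")
  if (length(name) != 1 || !name %in% valid)
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(valid, collapse = ", "))
  ref <- dvj_reference_measures()
  col <- if (name == "baseline") "mean_0h" else "mean_48h"
  val <- function(v) ref[[col]][ref$variable == v]
  condition_params(
    drop_height = 0.30,
    pelvic_tilt_ic = val("pelvis_tilt_ic_deg"),
    peak_pelvic_tilt = val("pelvis_tilt_peak_landing_deg"),
    hip_flexion_ic = val("hip_flexion_ic_deg"),
    peak_hip_flexion = val("hip_flexion_peak_landing_deg"),
    knee_flexion_ic = val("knee_flexion_ic_deg"),
    peak_knee_flexion = val("knee_flexion_peak_landing_deg"),
    ankle_ic = val("ankle_angle_ic_deg"),
    peak_ankle = val("ankle_angle_peak_landing_deg"),
    landing_duration = val("landing_duration_ms"),
    propulsion_duration = val("propulsion_duration_ms"),
    jump_height = val("jump_height_cm"),
    marker_noise_sd = marker_noise_sd,
    force_noise_sd = force_noise_sd,
    seed = seed
  )
}

#' Construct generator condition parameters
#'
#' Validates and packages the prescription the synthetic generator realizes:
#' angles in degrees, durations in ms, jump height in cm, drop height in m,
#' noise SDs in m (markers) and N (force).
#'
#' @param drop_height platform height in m
#' @param pelvic_tilt_ic,peak_pelvic_tilt anterior pelvic tilt at initial
#'   contact and its landing-phase peak (deg)
#' @param hip_flexion_ic,peak_hip_flexion hip flexion at initial contact and
#'   its landing-phase peak (deg)
#' @param knee_flexion_ic,peak_knee_flexion knee flexion at initial contact
#'   and its landing-phase peak (deg)
#' @param ankle_ic,peak_ankle ankle angle at initial contact and its
#'   landing-phase peak (deg, dorsiflexion positive)
#' @param landing_duration,propulsion_duration phase durations in ms
#' @param jump_height pelvis rise above standing at the flight apex, cm
#' @param marker_noise_sd,force_noise_sd i.i.d. Gaussian measurement noise
#'   SDs (m and N)
#' @param seed integer noise seed
#' @return an object of class `condition_params`
#' @export
condition_params <- function(drop_height = 0.30,
                             pelvic_tilt_ic, peak_pelvic_tilt,
                             hip_flexion_ic, peak_hip_flexion,
                             knee_flexion_ic, peak_knee_flexion,
                             ankle_ic, peak_ankle,
                             landing_duration, propulsion_duration,
                             jump_height,
                             marker_noise_sd = 5e-4, force_noise_sd = 2,
                             seed = 1L) {
  p <- list(
    drop_height = drop_height,
    pelvic_tilt_ic = pelvic_tilt_ic, peak_pelvic_tilt = peak_pelvic_tilt,
    hip_flexion_ic = hip_flexion_ic, peak_hip_flexion = peak_hip_flexion,
    knee_flexion_ic = knee_flexion_ic, peak_knee_flexion = peak_knee_flexion,
    ankle_ic = ankle_ic, peak_ankle = peak_ankle,
    landing_duration = landing_duration,
    propulsion_duration = propulsion_duration,
    jump_height = jump_height,
    marker_noise_sd = marker_noise_sd, force_noise_sd = force_noise_sd,
    seed = as.integer(seed)
  )
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("non-numeric condition parameter(s): ",
                      paste(names(p)[!num], collapse = ", "))
  if (p$drop_height <= 0) stop("infeasible params: drop_height must be > 0")
  if (p$landing_duration <= 0 || p$propulsion_duration <= 0)
    stop("infeasible params: phase durations must be > 0")
  if (p$marker_noise_sd < 0 || p$force_noise_sd < 0)
    stop("infeasible params: noise SDs must be >= 0")
  if (p$peak_knee_flexion < p$knee_flexion_ic)
    stop("infeasible params: peak knee flexion below initial-contact value")
  if (p$peak_hip_flexion < p$hip_flexion_ic)
    stop("infeasible params: peak hip flexion below initial-contact value")
  if (p$peak_pelvic_tilt < p$pelvic_tilt_ic)
    stop("infeasible params: peak pelvic tilt below initial-contact value")
  structure(p, class = "condition_params")
}
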
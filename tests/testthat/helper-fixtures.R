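# Shared fixtures, built once per test run and cached. All synthetic.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fx_subject <- function() fixture("subject", function() subject_spec(78.9, 1.811))

fx_static <- function() fixture("static", function()
  generate_static_trial(fx_subject(), marker_noise_sd = 0, force_noise_sd = 0))

fx_trial <- function(name) fixture(paste0("trial_", name), function()
  generate_dvj_trial(fx_subject(),
                     preset(name, marker_noise_sd = 0, force_noise_sd = 0)))

fx_analysis <- function(name) fixture(paste0("analysis_", name), function()
  analyze_trial(fx_trial(name), fx_static()))

fx_model <- function() fixture("model", function() build_body_model(fx_subject()))

# Events list shaped like detect_events() output, for direct unit tests.
fake_events <- function(idx_ic_kin, idx_takeoff_kin, rate_kin = 200,
                        rate_force = 1000) {
  structure(list(
    idx_ic_force = (idx_ic_kin - 1) * rate_force / rate_kin + 1,
    idx_takeoff_force = (idx_takeoff_kin - 1) * rate_force / rate_kin + 1,
    t_ic = (idx_ic_kin - 1) / rate_kin,
    t_takeoff = (idx_takeoff_kin - 1) / rate_kin,
    idx_ic_kin = idx_ic_kin, idx_takeoff_kin = idx_takeoff_kin,
    rate_kin = rate_kin, rate_force = rate_force
  ), class = "dvj_events")
}

# Minimal constant-pose trial from explicit right-leg planar marker
# positions (left leg mirrored), for constructed-geometry kinematics tests.
constant_pose_trial <- function(hip, knee, ankle, heel, toe, ant, post,
                                n = 8, subject = fx_subject()) {
  mk1 <- list(ankle = ankle, knee = knee, hip = hip, heel = heel, toe = toe,
              pelvis_ant = ant, pelvis_post = post)
  rep_mat <- function(v, z) matrix(c(rep(v[1], n), rep(v[2], n), rep(z, n)),
                                   n, 3)
  markers <- list(
    RASI = rep_mat(ant, 0.12), LASI = rep_mat(ant, -0.12),
    RPSI = rep_mat(post, 0.06), LPSI = rep_mat(post, -0.06),
    RHIP = rep_mat(hip, 0.09), LHIP = rep_mat(hip, -0.09),
    RKNE = rep_mat(knee, 0.09), LKNE = rep_mat(knee, -0.09),
    RANK = rep_mat(ankle, 0.09), LANK = rep_mat(ankle, -0.09),
    RHEE = rep_mat(heel, 0.09), LHEE = rep_mat(heel, -0.09),
    RTOE = rep_mat(toe, 0.09), LTOE = rep_mat(toe, -0.09)
  )
  nf <- (n - 1) * 5 + 1
  plate <- data.frame(time_s = (seq_len(nf) - 1) / 1000,
                      Fx_N = 0, Fy_N = subject$mass * 9.81 / 2, COPx_m = 0.05)
  trial_recording(markers = markers, rate_kin = 200,
                  plates = list(right = plate, left = plate),
                  rate_force = 1000, subject = subject, trial_kind = "static")
}
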
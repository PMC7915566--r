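test_that("generated trials realize the prescribed knee trajectory", {
  for (nm in c("baseline", "damaged48h")) {
    pr <- preset(nm, marker_noise_sd = 0, force_noise_sd = 0)
    truth <- attr(fx_trial(nm), "truth")
    in_contact <- truth$angles$time >= truth$t_ic &
      truth$angles$time < truth$t_to
    expect_equal(max(truth$angles$knee[in_contact]), pr$peak_knee_flexion,
                 tolerance = 0.01 / pr$peak_knee_flexion)
    # IC frame angle is exact (contact starts on a kinematic frame)
    i_ic <- which(abs(truth$angles$time - truth$t_ic) < 1e-9)
    expect_equal(truth$angles$knee[i_ic], pr$knee_flexion_ic,
                 tolerance = 1e-6)
  }
})

test_that("total vertical GRF is zero in flight and positive in contact", {
  truth <- attr(fx_trial("baseline"), "truth")
  tt <- (seq_along(truth$F_total) - 1) / 1000
  flight <- tt < truth$t_ic | tt >= truth$t_to
  expect_true(all(truth$F_total[flight] == 0))
  expect_true(all(truth$F_total[!flight] > 0))
})

test_that("contact-phase impulse equals the CoM momentum change within 1%", {
  for (nm in c("baseline", "damaged48h")) {
    trial <- fx_trial(nm)
    truth <- attr(trial, "truth")
    M <- trial$subject$mass
    F <- truth$F_total[truth$F_total != 0]
    dt <- 1 / trial$rate_force
    v <- diff(truth$com_contact$y) / dt   # numerical differentiation oracle
    impulse <- sum((head(F, -1) + tail(F, -1)) / 2) * dt -
      M * 9.81 * (length(F) - 1) * dt
    dmom <- M * (v[length(v)] - v[1])
    expect_lt(abs(impulse - dmom) / abs(dmom), 0.01)
  }
})

test_that("flight apex of the pelvis matches the prescribed jump height", {
  for (nm in c("baseline", "damaged48h")) {
    trial <- fx_trial(nm)
    truth <- attr(trial, "truth")
    y <- (trial$markers$RASI[, 2] + trial$markers$LASI[, 2] +
            trial$markers$RPSI[, 2] + trial$markers$LPSI[, 2]) / 4
    tt <- (seq_along(y) - 1) / trial$rate_kin
    apex <- max(y[tt > truth$t_to])
    h <- (apex - truth$y_pelvis_static) * 100
    expect_equal(h, attr(trial, "truth")$params$jump_height, tolerance = 0.2 /
                   attr(trial, "truth")$params$jump_height)
  }
})

test_that("identical seeds reproduce trials bitwise, different seeds do not", {
  subj <- fx_subject()
  a <- generate_dvj_trial(subj, preset("baseline", seed = 11))
  b <- generate_dvj_trial(subj, preset("baseline", seed = 11))
  c <- generate_dvj_trial(subj, preset("baseline", seed = 12))
  expect_identical(a$markers, b$markers)
  expect_identical(a$plates, b$plates)
  expect_false(identical(a$markers$RKNE, c$markers$RKNE))
})

test_that("infeasible prescriptions are rejected with diagnostics", {
  expect_error(preset("nonsense"), "valid presets")
  pr <- preset("baseline")
  expect_error(
    condition_params(
      drop_height = 0.3, pelvic_tilt_ic = 17, peak_pelvic_tilt = 20,
      hip_flexion_ic = 43, peak_hip_flexion = 61,
      knee_flexion_ic = 84, peak_knee_flexion = 42,   # peak below IC
      ankle_ic = -4, peak_ankle = 38,
      landing_duration = 134, propulsion_duration = 179, jump_height = 33),
    "peak knee flexion")
  expect_error(
    condition_params(
      drop_height = -1, pelvic_tilt_ic = 17, peak_pelvic_tilt = 20,
      hip_flexion_ic = 43, peak_hip_flexion = 61,
      knee_flexion_ic = 42, peak_knee_flexion = 84,
      ankle_ic = -4, peak_ankle = 38,
      landing_duration = 134, propulsion_duration = 179, jump_height = 33),
    "drop_height")
  # a hip excursion far larger than the knee's makes the touchdown shaping
  # overshoot the prescribed knee peak: dynamically infeasible, rejected
  lopsided <- condition_params(
    drop_height = 0.30, pelvic_tilt_ic = 15.61, peak_pelvic_tilt = 19.07,
    hip_flexion_ic = 32.27, peak_hip_flexion = 81.44,
    knee_flexion_ic = 43.23, peak_knee_flexion = 79.56,
    ankle_ic = 3.31, peak_ankle = 42.01,
    landing_duration = 162.03, propulsion_duration = 182.67,
    jump_height = 35.44, marker_noise_sd = 0, force_noise_sd = 0)
  expect_error(generate_dvj_trial(fx_subject(), lopsided), "infeasible")
})

test_that("static trial carries body weight and a neutral standing pose", {
  subj <- fx_subject()
  static <- fx_static()
  F_total <- static$plates$right$Fy_N + static$plates$left$Fy_N
  expect_equal(mean(F_total), subj$mass * 9.81, tolerance = 0.5 /
                 (subj$mass * 9.81))
  y <- (static$markers$RASI[, 2] + static$markers$LASI[, 2] +
          static$markers$RPSI[, 2] + static$markers$LPSI[, 2]) / 4
  expect_lt(diff(range(y)), 1e-9)
  ang <- joint_angles(static)
  for (col in c("pelvis", "hip", "knee", "ankle"))
    expect_lt(max(abs(ang[[col]])), 0.1)
})

test_that("presets reproduce the tabulated session parameters", {
  b <- preset("baseline")
  d <- preset("damaged48h")
  expect_equal(b$peak_knee_flexion, 84.15)
  expect_equal(d$peak_knee_flexion, 88.66)
  expect_equal(d$landing_duration + d$propulsion_duration, 381.7)
  expect_gt(d$peak_hip_flexion, b$peak_hip_flexion)
  expect_equal(d$peak_hip_flexion, 69.38)
})

test_that("muscle-damage panels recover the configured distributions", {
  # zero SDs: every subject sits exactly on the configured means
  flat <- eimd_reference_panel()
  flat$sd <- 0
  pan <- generate_eimd_panel(eimd_panel_params(panel = flat, n_subjects = 5))
  merged <- merge(pan, flat, by = c("indicator", "timepoint"))
  expect_equal(merged$value, merged$mean)

  # determinism
  p1 <- generate_eimd_panel(eimd_panel_params(seed = 9))
  p2 <- generate_eimd_panel(eimd_panel_params(seed = 9))
  expect_identical(p1, p2)

  # grand mean over replicate panels recovers the configured mean
  vals <- vapply(1:200, function(r) {
    pan <- generate_eimd_panel(eimd_panel_params(seed = r))
    mean(pan$value[pan$indicator == "IPT_pct" & pan$timepoint == "48h"])
  }, numeric(1))
  expect_lt(abs(mean(vals) - 80.5), 1)

  # soreness clipped to scale, CK non-negative
  pan <- generate_eimd_panel(eimd_panel_params(seed = 2, n_subjects = 50))
  expect_true(all(pan$value[pan$indicator == "DOMS"] >= 0 &
                    pan$value[pan$indicator == "DOMS"] <= 10))
  expect_true(all(pan$value[pan$indicator == "CK"] >= 0))

  bad <- eimd_reference_panel(); bad$sd[1] <- -1
  expect_error(eimd_panel_params(panel = bad), "SDs")
  expect_error(eimd_panel_params(n_subjects = 1), "n_subjects")
})
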
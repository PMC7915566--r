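test_that("neutral standing pose reads as zero at every joint", {
  ang <- joint_angles(fx_static())
  for (col in c("pelvis", "hip", "knee", "ankle"))
    expect_lt(max(abs(ang[[col]])), 0.1)
})

test_that("constructed geometry: shank rotated 60 deg from a vertical thigh", {
  hip <- c(0, 1.0)
  knee <- c(0, 0.55)
  # flexed knee with a vertical thigh: the ankle sits posterior and below
  ankle <- knee + 0.45 * c(-sin(60 * pi / 180), -cos(60 * pi / 180))
  heel <- ankle + c(-0.05, -0.07)
  toe <- ankle + c(0.15, -0.07)
  trial <- constant_pose_trial(hip, knee, ankle, heel, toe,
                               ant = c(0.08, 1.06), post = c(-0.08, 1.06))
  ang <- joint_angles(trial)
  expect_equal(ang$knee[1], 60, tolerance = 1e-6)
  expect_equal(ang$pelvis[1], 0, tolerance = 1e-6)
  expect_equal(ang$hip[1], 0, tolerance = 1e-6)
})

test_that("angles are invariant under global translation", {
  trial <- fx_static()
  shifted <- trial
  shifted$markers <- lapply(trial$markers, function(m)
    sweep(m, 2, c(0.31, 0.22, 0.05), "+"))
  a0 <- joint_angles(trial)
  a1 <- joint_angles(shifted)
  expect_equal(a1, a0, tolerance = 1e-9)
})

test_that("pipeline recovers the prescribed angles at initial contact", {
  res <- fx_analysis("baseline")
  pr <- preset("baseline")
  i0 <- res$events$idx_ic_kin
  expect_equal(res$angles$knee[i0], pr$knee_flexion_ic, tolerance = 0.2 /
                 pr$knee_flexion_ic)
  expect_lt(abs(res$angles$hip[i0] - pr$hip_flexion_ic), 0.25)
  expect_lt(abs(res$angles$pelvis[i0] - pr$pelvic_tilt_ic), 0.25)
  expect_lt(abs(res$angles$ankle[i0] - pr$ankle_ic), 0.25)
})

test_that("angular velocity matches analytic derivatives", {
  fake <- data.frame(time = (0:99) / 200, pelvis = 5, hip = 10,
                     knee = 90 * (0:99) / 200, ankle = 0)
  v <- angular_velocity(fake, 200)
  expect_equal(v$pelvis, rep(0, 100), tolerance = 1e-9)
  expect_equal(v$knee, rep(90, 100), tolerance = 1e-6)

  # quintic trajectory vs its analytic derivative
  co <- dvjmech:::quintic_coefs(40, 300, 0, 85, 0, -2000, 0.2)
  t <- seq(0, 0.2, by = 1 / 200)
  traj <- data.frame(time = t, pelvis = 0, hip = 0,
                     knee = dvjmech:::poly_eval(co, t), ankle = 0)
  v2 <- angular_velocity(traj, 200)
  truth <- dvjmech:::poly_eval(co, t, deriv = 1)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(v2$knee[interior] - truth[interior])), 0.5)
})

test_that("jump height reproduces the prescribed flight apex", {
  expect_equal(fx_analysis("baseline")$metrics$jump_height_cm, 33.38,
               tolerance = 0.2 / 33.38)

  pr <- preset("baseline", marker_noise_sd = 0, force_noise_sd = 0)
  pr$jump_height <- 20
  trial <- generate_dvj_trial(fx_subject(), pr)
  expect_equal(jump_height(trial, fx_static()), 20, tolerance = 0.2 / 20)
})

test_that("a trial without flight after contact is an error", {
  # a static recording never leaves the ground
  expect_error(jump_height(fx_static(), fx_static()), "no flight")
  # truncating the jump trial right after take-off removes the flight
  trial <- fx_trial("baseline")
  ev <- detect_events(trial)
  cut <- ev$idx_takeoff_kin
  trunc <- trial
  trunc$markers <- lapply(trial$markers, function(m) m[1:cut, , drop = FALSE])
  ratio <- trial$rate_force / trial$rate_kin
  nf <- (cut - 1) * ratio + 1
  trunc$plates <- lapply(trial$plates, function(p) p[1:nf, , drop = FALSE])
  ev2 <- detect_events(trunc)
  expect_error(jump_height(trunc, fx_static(), ev2), "no flight")
})

test_that("degenerate zero-length segments name the offending frame", {
  trial <- fx_static()
  broken <- trial
  broken$markers$RKNE <- broken$markers$RANK
  expect_error(joint_angles(broken), "frame 1")
})
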
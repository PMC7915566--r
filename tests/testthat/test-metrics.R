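test_that("phase split finds the earliest global knee-flexion maximum", {
  knee <- c(rep(10, 99), seq(40, 85, length.out = 36), seq(84, 20, length.out = 65))
  ev <- fake_events(idx_ic_kin = 100, idx_takeoff_kin = 200)
  ev <- split_phases(ev, knee)
  expect_equal(ev$idx_peak_kin, 135L)

  plateau <- knee
  plateau[131:136] <- 85
  ev2 <- split_phases(fake_events(100, 200), plateau)
  expect_equal(ev2$idx_peak_kin, 131L)   # earliest frame on ties

  rising <- seq(1, 300)
  expect_warning(split_phases(fake_events(100, 200), rising), "boundary")
})

test_that("knee stiffness uses the two phase-boundary instants", {
  n <- 200
  moment <- seq(0.50, 3.00, length.out = n)
  angle <- seq(41.61, 84.15, length.out = n)
  ev <- fake_events(1, n + 1)
  ev$idx_peak_kin <- n
  K <- knee_stiffness(moment, angle, ev)
  expect_equal(K, 2.50 / 42.54, tolerance = 1e-9)   # 0.0588 Nm/kg/deg

  expect_equal(knee_stiffness(rep(1, n), angle, ev), 0)
  expect_error(knee_stiffness(moment, rep(50, n), ev), "zero knee range")

  # peak-ratio mode uses phase extrema instead of the two instants
  hump <- c(seq(0.5, 3.5, length.out = 100), seq(3.5, 3.0, length.out = 100))
  K2 <- knee_stiffness(hump, angle, ev, mode = "peak_ratio")
  expect_equal(K2, 3.0 / 42.54, tolerance = 1e-9)
})

test_that("extracted metrics reproduce the prescription", {
  m <- fx_analysis("damaged48h")$metrics
  expect_equal(m$knee_flexion_peak_landing_deg, 88.66, tolerance = 0.1 / 88.66)
  mb <- fx_analysis("baseline")$metrics
  expect_equal(mb$contact_duration_ms, 313.2, tolerance = 2 / 313.2)
  expect_equal(mb$landing_duration_ms, 134.4, tolerance = 5 / 134.4)
  expect_equal(mb$propulsion_duration_ms, 178.8, tolerance = 5 / 178.8)
})

test_that("phase durations are additive to within one kinematic frame", {
  for (nm in c("baseline", "damaged48h")) {
    m <- fx_analysis(nm)$metrics
    expect_lte(abs(m$landing_duration_ms + m$propulsion_duration_ms -
                     m$contact_duration_ms), 5)
  }
  noisy <- generate_dvj_trial(fx_subject(), preset("baseline", seed = 5))
  m <- analyze_trial(noisy, fx_static())$metrics
  expect_lte(abs(m$landing_duration_ms + m$propulsion_duration_ms -
                   m$contact_duration_ms), 5)
})

test_that("stiffness is consistent with the extracted instants", {
  res <- fx_analysis("baseline")
  ev <- res$events
  K <- (res$kinetics$knee_moment_nmkg[ev$idx_peak_kin] -
          res$kinetics$knee_moment_nmkg[ev$idx_ic_kin]) /
    (res$angles$knee[ev$idx_peak_kin] - res$angles$knee[ev$idx_ic_kin])
  expect_equal(res$metrics$knee_stiffness_nmkg_deg, K, tolerance = 1e-12)
})

test_that("larger prescribed peak flexion extracts as larger peak flexion", {
  mb <- fx_analysis("baseline")$metrics
  md <- fx_analysis("damaged48h")$metrics
  expect_gt(md$knee_flexion_peak_landing_deg, mb$knee_flexion_peak_landing_deg)
})

test_that("trial averaging is the field-wise mean", {
  m <- fx_analysis("baseline")$metrics
  expect_equal(average_trials(list(m, m, m)), m, ignore_attr = TRUE)
  m1 <- m; m2 <- m; m3 <- m
  m1$jump_height_cm <- 1; m2$jump_height_cm <- 2; m3$jump_height_cm <- 3
  expect_equal(average_trials(list(m1, m2, m3))$jump_height_cm, 2)
  expect_error(average_trials(list()), "no trial metrics")
})

test_that("averaging three noisy trials beats a single trial most of the time", {
  knee_peak <- function(trial) {
    ev <- detect_events(trial)
    ang <- joint_angles(filter_trial(trial))
    ev <- split_phases(ev, ang$knee)
    max(ang$knee[ev$idx_ic_kin:ev$idx_peak_kin])
  }
  ref <- knee_peak(fx_trial("baseline"))   # noise-free pipeline value
  subj <- fx_subject()
  reps <- 60
  wins <- vapply(seq_len(reps), function(r) {
    vals <- vapply(1:3, function(k)
      knee_peak(generate_dvj_trial(subj, preset("baseline",
                                                seed = 1000 * r + k))),
      numeric(1))
    abs(mean(vals) - ref) < abs(vals[1] - ref)
  }, logical(1))
  expect_gte(mean(wins), 0.6)
})
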
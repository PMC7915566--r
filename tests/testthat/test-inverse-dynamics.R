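# Closed-form static joint moments about joint J for the standing pose:
# internal moment = reported-convention sign of the net external torque
# (GRF at the COP plus the weights of the segments distal to J).
static_closed_form <- function(trial, model, Fy, copx) {
  g <- 9.81
  at <- function(m) trial$markers[[m]][1, 1:2]
  hee <- at("RHEE"); toe <- at("RTOE"); ank <- at("RANK")
  kne <- at("RKNE"); hip <- at("RHIP")
  seg <- function(s) dvjmech:::model_segment(model, s)
  f <- seg("foot"); s <- seg("shank"); t <- seg("thigh")
  comf <- hee + f$com_fraction * (toe - hee)
  coms <- kne + s$com_fraction * (ank - kne)
  comt <- hip + t$com_fraction * (kne - hip)
  list(
    ankle = Fy * (copx - ank[1]) - f$mass * g * (comf[1] - ank[1]),
    knee = -(Fy * (copx - kne[1]) - f$mass * g * (comf[1] - kne[1]) -
               s$mass * g * (coms[1] - kne[1])),
    hip = Fy * (copx - hip[1]) - f$mass * g * (comf[1] - hip[1]) -
      s$mass * g * (coms[1] - hip[1]) - t$mass * g * (comt[1] - hip[1])
  )
}

test_that("anthropometric tables give published segment parameters", {
  model <- fx_model()
  shank <- dvjmech:::model_segment(model, "shank")
  expect_equal(shank$mass, 78.9 * 0.0433, tolerance = 1e-9)  # 3.416 kg
  for (tab in c("deleva1996", "dempster1955")) {
    m <- build_body_model(fx_subject(), table = tab)
    fr <- m$segments
    total <- 2 * sum(fr$mass_fraction[fr$segment != "head_arms_trunk"]) +
      fr$mass_fraction[fr$segment == "head_arms_trunk"]
    expect_lt(abs(total - 1), 1e-3)
  }
  expect_error(build_body_model(fx_subject(), table = "winter"), "winter")
  expect_error(subject_spec(mass = 0), "positive")
})

test_that("static standing moments match the closed-form lever arms", {
  trial <- fx_static()
  model <- fx_model()
  n <- nrow(trial$markers$RANK)
  M <- trial$subject$mass
  Fy <- M * 9.81 / 2
  copx <- trial$markers$RANK[1, 1] + 0.05   # COP 5 cm anterior to the ankle
  grf <- data.frame(Fx_N = rep(0, n), Fy_N = rep(Fy, n),
                    COPx_m = rep(copx, n))
  kin <- newton_euler_planar(trial, model, grf)
  cf <- static_closed_form(trial, model, Fy, copx)
  mid <- round(n / 2)
  expect_equal(kin$ankle_moment_nm[mid], cf$ankle,
               tolerance = 0.005)
  expect_equal(kin$knee_moment_nm[mid], cf$knee, tolerance = 0.005)
  expect_equal(kin$hip_moment_nm[mid], cf$hip, tolerance = 0.005)
  # the GRF lever term alone: half body weight times the 5 cm arm
  expect_equal(cf$ankle +
                 dvjmech:::model_segment(model, "foot")$mass * 9.81 *
                 (trial$markers$RHEE[1, 1] + 0.4415 *
                    (trial$markers$RTOE[1, 1] - trial$markers$RHEE[1, 1]) -
                    trial$markers$RANK[1, 1]),
               0.5 * M * 9.81 * 0.05, tolerance = 1e-6)
})

test_that("a foot swinging about a fixed ankle matches the pendulum form", {
  subject <- fx_subject()
  model <- fx_model()
  n <- 400
  t <- (seq_len(n) - 1) / 200
  pitch <- 20 * sin(2 * pi * 1 * t)          # deg
  ank <- c(0, subject$segment_lengths$ankle_height)
  mk <- dvjmech:::fk_markers(
    list(pelvis = rep(0, n), hip = rep(0, n), knee = rep(0, n),
         ankle = pitch),
    matrix(ank, n, 2, byrow = TRUE), subject)
  trial <- fx_static()
  swing <- trial
  swing$markers <- lapply(trial$markers, function(m)
    m[rep(1, n), , drop = FALSE])
  for (m in c("RHEE", "LHEE"))
    swing$markers[[m]][, 1:2] <- mk$heel
  for (m in c("RTOE", "LTOE"))
    swing$markers[[m]][, 1:2] <- mk$toe
  nf <- (n - 1) * 5 + 1
  swing$plates <- lapply(swing$plates, function(p) {
    p <- p[rep(1, nf), ]
    p$time_s <- (seq_len(nf) - 1) / 1000
    p$Fy_N <- 0; p$Fx_N <- 0
    p
  })
  grf <- data.frame(Fx_N = rep(0, n), Fy_N = rep(0, n), COPx_m = rep(0, n))
  kin <- newton_euler_planar(swing, model, grf)

  f <- dvjmech:::model_segment(model, "foot")
  hee <- swing$markers$RHEE[, 1:2]; toe <- swing$markers$RTOE[, 1:2]
  comf <- hee + f$com_fraction * (toe - hee)
  d2 <- derivative(pitch * pi / 180, 200, 2)
  rx <- comf[, 1] - ank[1]
  ry <- comf[, 2] - ank[2]
  I_piv <- f$inertia + f$mass * (rx^2 + ry^2)
  closed <- -(I_piv * d2 + f$mass * 9.81 * rx)   # plantarflexion positive
  core <- 20:(n - 20)
  scale <- max(abs(closed[core]))
  expect_lt(max(abs(kin$ankle_moment_nm[core] - closed[core])) / scale, 0.01)
})

test_that("moments are linear in the applied GRF", {
  trial <- fx_static()
  model <- fx_model()
  n <- nrow(trial$markers$RANK)
  copx <- trial$markers$RANK[1, 1] + 0.08
  mk_grf <- function(s) data.frame(Fx_N = rep(0, n),
                                   Fy_N = rep(s * 400, n),
                                   COPx_m = rep(copx, n))
  k1 <- newton_euler_planar(trial, model, mk_grf(1))
  k2 <- newton_euler_planar(trial, model, mk_grf(2))
  k0 <- newton_euler_planar(trial, model, mk_grf(0))
  expect_equal(k2$knee_moment_nm - k1$knee_moment_nm,
               k1$knee_moment_nm - k0$knee_moment_nm, tolerance = 1e-9)
  expect_equal(k2$hip_moment_nm - k1$hip_moment_nm,
               k1$hip_moment_nm - k0$hip_moment_nm, tolerance = 1e-9)
})

test_that("normalization round-trips exactly and powers follow conventions", {
  res <- fx_analysis("damaged48h")
  M <- fx_subject()$mass
  expect_equal(res$kinetics$knee_moment_nmkg * M, res$kinetics$knee_moment_nm,
               tolerance = 1e-12)

  kin <- data.frame(ankle_moment_nm = 0, knee_moment_nm = 2 * M,
                    hip_moment_nm = 0)
  vel <- data.frame(pelvis = 0, hip = 0,
                    knee = -1 / (pi / 180), ankle = 0)  # extending, 1 rad/s
  out <- joint_power(kin, vel, M)
  expect_equal(out$knee_power_wkg, 2, tolerance = 1e-9)
  vel0 <- data.frame(pelvis = 0, hip = 0, knee = 0, ankle = 0)
  expect_equal(joint_power(kin, vel0, M)$knee_power_wkg, 0)
})

test_that("landing kinetics show the expected sign pattern", {
  for (nm in c("baseline", "damaged48h")) {
    m <- fx_analysis(nm)$metrics
    expect_gt(m$knee_moment_peak_landing_nmkg, 0)   # internal extension
    expect_lt(m$knee_power_absorption_landing_wkg, 0)  # eccentric
    expect_gt(m$knee_power_generation_propulsion_wkg, 0)
    expect_gt(m$ankle_moment_peak_landing_nmkg, 0)
    expect_gt(m$grf_peak_landing_bw, 1)             # above body weight
  }
})
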
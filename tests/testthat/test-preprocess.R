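test_that("contact detection is exact on step inputs", {
  f <- c(rep(0, 100), rep(500, 400))
  iv <- detect_contact_events(f, 1000)
  expect_equal(iv$start, 101)        # first sample strictly above threshold
  expect_equal(iv$end, 501)          # half-open: past the last sample
  expect_equal(attr(iv, "analyzed"), 1)

  # plateau ending mid-series
  f2 <- c(rep(0, 100), rep(500, 300), rep(0, 200))
  iv2 <- detect_contact_events(f2, 1000)
  expect_equal(unname(c(iv2$start, iv2$end)), c(101, 401))
})

test_that("plate noise alone never triggers a contact", {
  set.seed(41)
  f <- rnorm(1000, 0, 2)
  expect_error(detect_contact_events(f, 1000), "no contact detected")
})

test_that("detected contact duration matches the prescription to one sample", {
  for (nm in c("baseline", "damaged48h")) {
    trial <- fx_trial(nm)
    truth <- attr(trial, "truth")
    ev <- detect_events(trial)
    prescribed <- (truth$t_to - truth$t_ic) * 1000
    detected <- (ev$t_takeoff - ev$t_ic) * 1000
    expect_lte(abs(detected - prescribed), 1)
    expect_equal(ev$t_ic, truth$t_ic)
  }
})

test_that("event indices are debounce-robust to 2 N plate noise", {
  trial <- fx_trial("baseline")
  ev0 <- detect_events(trial)
  noisy <- trial
  set.seed(7)
  for (pl in names(noisy$plates))
    noisy$plates[[pl]]$Fy_N <- noisy$plates[[pl]]$Fy_N +
      rnorm(nrow(noisy$plates[[pl]]), 0, 2)
  ev1 <- detect_events(noisy)
  expect_lte(abs(ev1$idx_ic_force - ev0$idx_ic_force), 1)
  expect_lte(abs(ev1$idx_takeoff_force - ev0$idx_takeoff_force), 1)
})

test_that("zero-lag Butterworth has unit DC gain and 0.5 gain at cutoff", {
  x <- rep(3.7, 500)
  expect_equal(butterworth_lowpass(x, 1000), x, tolerance = 1e-6)

  t <- (0:9999) / 1000
  s15 <- sin(2 * pi * 15 * t)
  y <- butterworth_lowpass(s15, 1000, cutoff = 15, order = 4)
  core <- 2000:8000
  gain <- max(abs(y[core]))
  expect_equal(gain, 0.5, tolerance = 0.01 / 0.5)

  s80 <- sin(2 * pi * 80 * t)
  y80 <- butterworth_lowpass(s80, 1000, cutoff = 15, order = 4)
  expect_lt(max(abs(y80[core])), 0.01)

  expect_error(butterworth_lowpass(rnorm(10), 1000), "too short")
  expect_error(butterworth_lowpass(rnorm(100), 25, cutoff = 15), "twice")
})

test_that("filtering is idempotent on band-limited signals within 1%", {
  t <- (0:1999) / 1000
  x <- sin(2 * pi * 3 * t) + 0.5 * cos(2 * pi * 5 * t)
  once <- butterworth_lowpass(x, 1000)
  twice <- butterworth_lowpass(once, 1000)
  core <- 300:1700
  expect_lt(max(abs(twice[core] - once[core])) / max(abs(once[core])), 0.01)
})

test_that("force decimation keeps values, length and low-band content", {
  x <- rep(500, 1000)
  y <- downsample_force_to_kin(x, 1000, 200)
  expect_equal(length(y), 200)
  expect_equal(y, rep(500, 200), tolerance = 1e-6)

  # analytic dual-pass gain at 5 Hz with a 15 Hz cutoff:
  # 1 / (1 + (5/15)^4) = 0.9878, i.e. a 1.2% droop
  t <- (0:4999) / 1000
  s <- sin(2 * pi * 5 * t)
  y5 <- downsample_force_to_kin(s, 1000, 200)
  direct <- sin(2 * pi * 5 * (0:999) / 200)
  core <- 100:900
  expect_lt(max(abs(y5[core] - direct[core])), 0.015)

  expect_error(downsample_force_to_kin(x, 1000, 300), "integer multiple")
})

test_that("central-difference derivatives are exact for low-order inputs", {
  t <- (0:199) / 200
  expect_equal(derivative(3 * t, 200, 1), rep(3, 200), tolerance = 1e-9)
  d2 <- derivative(t^2, 200, 2)
  expect_equal(d2[2:199], rep(2, 198), tolerance = 1e-6)

  # analytic central-difference error for sin(2*pi*t) at 200 Hz:
  # |cos|(2*pi - sin(2*pi*h)/h) = 1.04e-3
  s <- sin(2 * pi * t)
  ds <- derivative(s, 200, 1)
  expect_lt(max(abs(ds[2:199] - 2 * pi * cos(2 * pi * t[2:199]))), 1.1e-3)

  expect_error(derivative(1:2, 200), "too short")
})
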
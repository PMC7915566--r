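# Event detection on raw force, zero-lag low-pass filtering, rate
# alignment, and numerical differentiation.
#
# Ordering contract: contact events are detected on the RAW vertical GRF;
# marker trajectories and forces are filtered afterwards.

#' Zero-lag Butterworth low-pass filter
#'
#' Dual-pass (forward and backward) Butterworth filtering with odd
#' reflective edge padding. With `order_interpretation = "net"` (default)
#' the nominal order is the net order after the dual pass, i.e. each pass
#' is a Butterworth of half the nominal order — the dominant biomechanics
#' convention for a "4th-order zero-lag" filter. `"per_pass"` applies the
#' full nominal order in each direction instead.
#'
#' @param x numeric series
#' @param rate sampling rate, Hz (must exceed twice the cutoff)
#' @param cutoff low-pass cutoff, Hz
#' @param order nominal filter order (even for `"net"`)
#' @param order_interpretation `"net"` or `"per_pass"`
#' @return filtered series, same length as `x`
#' @examples
#' butterworth_lowpass(sin(2 * pi * 40 * (0:999) / 1000), 1000)
#' @export
butterworth_lowpass <- function(x, rate, cutoff = 15, order = 4,
                                order_interpretation = c("net", "per_pass")) {
  order_interpretation <- match.arg(order_interpretation)
  if (rate <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  n <- length(x)
  if (n < 3 * (order + 1))
    stop("series too short to filter: need at least ", 3 * (order + 1),
         " samples, got ", n)
  pass_order <- if (order_interpretation == "net") {
    if (order %% 2 != 0) stop("net order must be even")
    order / 2
  } else order
  bf <- signal::butter(pass_order, 2 * cutoff / rate, type = "low")
  pad <- min(n - 1, 3 * ceiling(rate / cutoff))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Detect foot-ground contact intervals on raw vertical GRF
#'
#' Maximal intervals where the raw total vertical force exceeds the
#' threshold, debounced: sub-debounce gaps between above-threshold runs are
#' merged, then sub-debounce runs are discarded. Intervals are half-open at
#' the force rate: `start` is the first sample strictly above the
#' threshold, `end` the first subsequent sample at or below it.
#'
#' @param f raw total vertical GRF series, N, at `rate` Hz
#' @param rate force sampling rate, Hz
#' @param threshold contact threshold, N
#' @param debounce debounce window, s
#' @param min_contact minimum duration, s, for an interval to qualify as the
#'   analyzed landing contact
#' @return data frame of intervals (`start`, `end`, 1-based sample indices,
#'   `end` exclusive) with attribute `analyzed` giving the row index of the
#'   first interval of duration >= `min_contact`
#' @examples
#' f <- c(rep(0, 100), rep(500, 300), rep(0, 100))
#' detect_contact_events(f, 1000)
#' @export
detect_contact_events <- function(f, rate, threshold = 10, debounce = 0.020,
                                  min_contact = 0.100) {
  if (length(f) < 2) stop("force series too short")
  above <- f > threshold
  db <- max(1, round(debounce * rate))
  r <- rle(above)
  # merge sub-debounce gaps between above-threshold runs
  if (length(r$lengths) > 2) {
    inner <- 2:(length(r$lengths) - 1)
    short_gap <- rep(FALSE, length(r$lengths))
    short_gap[inner] <- !r$values[inner] & r$lengths[inner] < db
    if (any(short_gap)) {
      r$values[short_gap] <- TRUE
      r <- rle(rep(r$values, r$lengths))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= db
  if (!any(keep)) stop("no contact detected")
  iv <- data.frame(start = starts[keep], end = ends[keep] + 1L)
  dur <- (iv$end - iv$start) / rate
  analyzed <- which(dur >= min_contact)
  if (length(analyzed) == 0) stop("no contact detected")
  attr(iv, "analyzed") <- analyzed[1]
  iv
}

#' Filter then decimate a force-rate series to the kinematic rate
#'
#' Low-pass filters at the shared cutoff, then keeps every
#' `rate_force / rate_kin`-th sample starting at the first.
#'
#' @param x series at `rate_force`
#' @param rate_force,rate_kin sampling rates, Hz (integer ratio)
#' @param cutoff low-pass cutoff, Hz
#' @param order nominal filter order
#' @return series at `rate_kin`
#' @export
downsample_force_to_kin <- function(x, rate_force, rate_kin, cutoff = 15,
                                    order = 4) {
  if (rate_force %% rate_kin != 0)
    stop("rate_force must be an integer multiple of rate_kin")
  y <- butterworth_lowpass(x, rate_force, cutoff = cutoff, order = order)
  y[seq(1, length(y), by = rate_force / rate_kin)]
}

#' Numerical derivative by central differences
#'
#' Central differences in the interior, one-sided at the edges; output has
#' the same length as the input. Exact for quadratics in the interior.
#'
#' @param x series
#' @param rate sampling rate, Hz
#' @param order derivative order, 1 or 2
#' @return differentiated series
#' @export
derivative <- function(x, rate, order = 1) {
  n <- length(x)
  if (n < 3) stop("series too short to differentiate (need >= 3 samples)")
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")
  if (order == 1) {
    d <- c(x[2] - x[1],
           (x[3:n] - x[1:(n - 2)]) / 2,
           x[n] - x[n - 1]) * rate
  } else {
    core <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * rate^2
    d <- c(core[1], core, core[n - 2])
  }
  d
}

#' Low-pass filter all channels of a trial
#'
#' Filters every marker coordinate and every plate force channel with the
#' zero-lag Butterworth filter (COP is left unfiltered). Event detection
#' must use the raw trial; this is enforced by detecting events before
#' filtering in [analyze_trial()].
#'
#' @param trial a [trial_recording()]
#' @param cutoff low-pass cutoff, Hz
#' @param order nominal filter order
#' @param order_interpretation see [butterworth_lowpass()]
#' @return the filtered `trial_recording` (attribute `filtered` set)
#' @export
filter_trial <- function(trial, cutoff = 15, order = 4,
                         order_interpretation = "net") {
  validate_trial_recording(trial)
  trial$markers <- lapply(trial$markers, function(m)
    apply(m, 2, butterworth_lowpass, rate = trial$rate_kin, cutoff = cutoff,
          order = order, order_interpretation = order_interpretation))
  trial$plates <- lapply(trial$plates, function(p) {
    p$Fy_N <- butterworth_lowpass(p$Fy_N, trial$rate_force, cutoff, order,
                                  order_interpretation)
    p$Fx_N <- butterworth_lowpass(p$Fx_N, trial$rate_force, cutoff, order,
                                  order_interpretation)
    p
  })
  attr(trial, "filtered") <- TRUE
  trial
}

#' Detect the analyzed contact and express it at both rates
#'
#' Runs [detect_contact_events()] on the raw total vertical GRF and maps
#' the analyzed contact interval to kinematic-rate frame indices.
#'
#' @param trial a raw (unfiltered) `trial_recording`
#' @param threshold,debounce,min_contact see [detect_contact_events()]
#' @return an object of class `dvj_events`: force-rate indices
#'   (`idx_ic_force`, `idx_takeoff_force`), kinematic-rate indices
#'   (`idx_ic_kin`, `idx_takeoff_kin`) and times (`t_ic`, `t_takeoff`, s)
#' @export
detect_events <- function(trial, threshold = 10, debounce = 0.020,
                          min_contact = 0.100) {
  f <- total_vertical_grf(trial)
  iv <- detect_contact_events(f, trial$rate_force, threshold = threshold,
                              debounce = debounce, min_contact = min_contact)
  a <- attr(iv, "analyzed")
  idx_ic_f <- iv$start[a]
  idx_to_f <- iv$end[a]
  t_ic <- (idx_ic_f - 1) / trial$rate_force
  t_to <- (idx_to_f - 1) / trial$rate_force
  structure(list(
    idx_ic_force = idx_ic_f, idx_takeoff_force = idx_to_f,
    t_ic = t_ic, t_takeoff = t_to,
    idx_ic_kin = as.integer(ceiling(t_ic * trial$rate_kin - 1e-9)) + 1L,
    idx_takeoff_kin = as.integer(ceiling(t_to * trial$rate_kin - 1e-9)) + 1L,
    rate_kin = trial$rate_kin, rate_force = trial$rate_force,
    intervals = iv
  ), class = "dvj_events")
}
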
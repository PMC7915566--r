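# Trial container and file input/output.
#
# Marker trajectories travel as TRC-dialect tab-separated text (rate and
# units self-described in the header), per-plate forces as CSV
# (time_s, Fx_N, Fy_N, COPx_m), subject metadata as YAML. All downstream
# modules consume only the validated `trial_recording`; nothing re-parses
# files.

REQUIRED_MARKERS <- c("RASI", "LASI", "RPSI", "LPSI",
                      "RHIP", "RKNE", "RANK", "RHEE", "RTOE")

#' Construct and validate a trial recording
#'
#' Synchronized container for one static or DVJ trial: marker trajectories
#' (m) at the kinematic rate, per-plate force channels (N, COP in m) at the
#' force rate, and the subject record. Marker and force streams share
#' `t = 0`; sample `i` is at time `(i - 1) / rate`.
#'
#' @param markers named list of n x 3 matrices (x anterior, y vertical up,
#'   z mediolateral, in m)
#' @param rate_kin kinematic sampling rate, Hz
#' @param plates named list of data frames with columns `time_s`, `Fx_N`,
#'   `Fy_N`, `COPx_m`
#' @param rate_force force sampling rate, Hz; integer multiple of `rate_kin`
#' @param subject a [subject_spec()]
#' @param trial_kind `"static"` or `"dvj"`
#' @return an object of class `trial_recording`
#' @export
trial_recording <- function(markers, rate_kin, plates, rate_force, subject,
                            trial_kind = c("dvj", "static")) {
  trial_kind <- match.arg(trial_kind)
  x <- structure(
    list(markers = markers, rate_kin = rate_kin, plates = plates,
         rate_force = rate_force, subject = subject,
         trial_kind = trial_kind),
    class = "trial_recording"
  )
  validate_trial_recording(x)
  x
}

validate_trial_recording <- function(x) {
  stopifnot(inherits(x, "trial_recording"))
  if (!is.numeric(x$rate_kin) || x$rate_kin <= 0)
    stop("rate_kin must be > 0")
  if (x$rate_force < x$rate_kin)
    stop("rate_force must be >= rate_kin")
  if (x$rate_force %% x$rate_kin != 0)
    stop("rate_force must be an integer multiple of rate_kin ",
         "(got ", x$rate_force, " / ", x$rate_kin, ")")
  if (length(x$plates) < 1) stop("trial has no force plates")
  missing <- setdiff(REQUIRED_MARKERS, names(x$markers))
  if (length(missing) > 0)
    stop("required marker label(s) missing: ", paste(missing, collapse = ", "))
  n <- unique(vapply(x$markers, nrow, integer(1)))
  if (length(n) != 1) stop("marker series have unequal lengths")
  if (any(vapply(x$markers, function(m) anyNA(m), logical(1))))
    stop("marker series contain unfilled gaps")
  cols <- c("time_s", "Fx_N", "Fy_N", "COPx_m")
  ok <- vapply(x$plates, function(p) all(cols %in% names(p)), logical(1))
  if (!all(ok)) stop("force plate data must have columns ",
                     paste(cols, collapse = ", "))
  if (!inherits(x$subject, "subject_spec")) stop("subject must be a subject_spec")
  invisible(x)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %s: %d markers x %d frames @ %g Hz, %d plate(s) @ %g Hz\n",
    x$trial_kind, length(x$markers), nrow(x$markers[[1]]), x$rate_kin,
    length(x$plates), x$rate_force))
  invisible(x)
}

n_frames <- function(trial) nrow(trial$markers[[1]])

marker_xy <- function(trial, label) {
  m <- trial$markers[[label]]
  if (is.null(m)) stop("required marker label missing: ", label)
  m[, 1:2, drop = FALSE]
}

# Raw total vertical GRF (sum over plates), at the force rate.
total_vertical_grf <- function(trial) {
  Reduce(`+`, lapply(trial$plates, function(p) p$Fy_N))
}

#' Write a trial to disk
#'
#' Emits a TRC-dialect marker file (`markers.trc`, positions in mm), one
#' force CSV per plate (`forces_<plate>.csv`) and a YAML subject file
#' (`subject.yaml`), all readable by [read_trial()].
#'
#' @param trial a [trial_recording()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, the named list of written file paths
#' @export
write_trial <- function(trial, out_dir) {
  validate_trial_recording(trial)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  labels <- names(trial$markers)
  n <- n_frames(trial)
  marker_path <- file.path(out_dir, "markers.trc")
  con <- file(marker_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    paste("PathFileType", "4", "(X/Y/Z)", "markers.trc", sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(trial$rate_kin, trial$rate_kin, n, length(labels), "mm",
          trial$rate_kin, 1, n, sep = "\t"),
    paste(c("Frame#", "Time",
            unlist(lapply(labels, function(l) c(l, "", "")))), collapse = "\t"),
    paste(c("", "", unlist(lapply(seq_along(labels), function(i)
      paste0(c("X", "Y", "Z"), i)))), collapse = "\t")
  ), con)
  dat <- do.call(cbind, lapply(trial$markers, function(m) m * 1000))
  times <- (seq_len(n) - 1) / trial$rate_kin
  body <- cbind(seq_len(n), round(times, 6), round(dat, 4))
  utils::write.table(body, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)

  force_paths <- vapply(names(trial$plates), function(pl) {
    p <- file.path(out_dir, paste0("forces_", pl, ".csv"))
    utils::write.csv(trial$plates[[pl]], p, row.names = FALSE)
    p
  }, character(1))

  subject_path <- file.path(out_dir, "subject.yaml")
  yaml::write_yaml(list(mass_kg = trial$subject$mass,
                        height_m = trial$subject$height,
                        trial_kind = trial$trial_kind), subject_path)
  invisible(list(markers = marker_path, forces = force_paths,
                 subject = subject_path))
}

#' Read a trial from disk
#'
#' Parses a TRC-dialect marker file, per-plate force CSVs and the subject
#' YAML into a validated [trial_recording()]. Positions are normalized to m
#' (TRC files declaring mm are converted); marker dropouts of up to 10
#' frames are filled with a cubic spline through the neighbouring samples,
#' longer gaps are an error.
#'
#' @param marker_path TRC marker file
#' @param force_paths character vector of force CSV paths; names become the
#'   plate ids (unnamed paths are named `plate1`, `plate2`, ...)
#' @param subject_path subject YAML file
#' @param max_gap largest fillable marker dropout, in frames
#' @return a `trial_recording`
#' @export
read_trial <- function(marker_path, force_paths, subject_path,
                       max_gap = 10) {
  for (f in c(marker_path, force_paths, subject_path))
    if (!file.exists(f)) stop("file not found: ", f)

  lines <- readLines(marker_path)
  if (length(lines) < 6) stop("TRC file too short: ", marker_path)
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- setNames(as.list(hdr_vals), hdr_names)
  if (is.null(hdr$Units) || !nzchar(hdr$Units))
    stop("TRC header lacks a Units field")
  unit_scale <- switch(hdr$Units, mm = 1e-3, m = 1,
                       stop("unsupported TRC units: ", hdr$Units))
  rate_kin <- as.numeric(hdr$DataRate)
  if (!is.finite(rate_kin) || rate_kin <= 0)
    stop("TRC header lacks a valid DataRate")
  label_row <- strsplit(lines[4], "\t")[[1]]
  labels <- label_row[-(1:2)]
  labels <- labels[nzchar(labels)]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  fields <- strsplit(data_lines, "\t")
  ncol_expect <- 2 + 3 * length(labels)
  dat <- t(vapply(fields, function(f) {
    f <- c(f, rep("", max(0, ncol_expect - length(f))))
    suppressWarnings(as.numeric(f[seq_len(ncol_expect)]))
  }, numeric(ncol_expect)))
  n <- nrow(dat)

  markers <- list()
  for (i in seq_along(labels)) {
    block <- dat[, 2 + (3 * (i - 1) + 1):(3 * i), drop = FALSE] * unit_scale
    block <- apply(block, 2, fill_marker_gaps, max_gap = max_gap,
                   label = labels[i])
    markers[[labels[i]]] <- block
  }

  if (length(force_paths) == 0) stop("no force files given")
  if (is.null(names(force_paths)) || any(!nzchar(names(force_paths))))
    names(force_paths) <- paste0("plate", seq_along(force_paths))
  plates <- lapply(force_paths, function(p) utils::read.csv(p))
  dt <- diff(plates[[1]]$time_s[1:2])
  rate_force <- round(1 / dt)

  meta <- yaml::read_yaml(subject_path)
  subject <- subject_spec(mass = meta$mass_kg, height = meta$height_m)
  kind <- if (!is.null(meta$trial_kind)) meta$trial_kind else "dvj"

  trial_recording(markers = markers, rate_kin = rate_kin, plates = plates,
                  rate_force = rate_force, subject = subject,
                  trial_kind = kind)
}

# Cubic-spline fill of short dropouts (NA runs of at most max_gap frames).
fill_marker_gaps <- function(x, max_gap, label) {
  if (!anyNA(x)) return(x)
  na_runs <- rle(is.na(x))
  if (max(na_runs$lengths[na_runs$values]) > max_gap)
    stop("marker '", label, "' has a dropout longer than ", max_gap,
         " frames")
  idx <- which(!is.na(x))
  if (length(idx) < 4) stop("marker '", label, "' has too few samples to fill")
  filled <- stats::spline(idx, x[idx], xout = seq_along(x), method = "fmm")$y
  x[is.na(x)] <- filled[is.na(x)]
  x
}
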
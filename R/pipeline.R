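# Study orchestration: configuration, the pre/post cohort pipeline and the
# metric-level cohort power simulation.

#' Pipeline configuration
#'
#' All tunable parameters of the analysis pipeline with their standard
#' defaults: 10 N contact threshold, 15 Hz cutoff, net 4th-order zero-lag
#' Butterworth, 20 ms event debounce, 100 ms minimum contact, de Leva
#' anthropometrics, stiffness from the two phase-boundary instants,
#' dominant-side analysis, alpha 0.05 and a within-subject session
#' correlation of 0.8 for cohort simulation.
#'
#' @param ... overrides for any configuration field
#' @return named list of class `dvj_config`
#' @export
dvj_config <- function(...) {
  cfg <- list(
    threshold = 10, cutoff = 15, filter_order = 4,
    order_interpretation = "net", debounce = 0.020, min_contact = 0.100,
    anthropometric_table = "deleva1996", stiffness_mode = "instants",
    dominant_side = "right", alpha = 0.05, session_correlation = 0.8
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "dvj_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!cfg$anthropometric_table %in% c("deleva1996", "dempster1955"))
    stop("unknown anthropometric_table: '", cfg$anthropometric_table,
         "' (valid: deleva1996, dempster1955)")
  if (!cfg$stiffness_mode %in% c("instants", "peak_ratio"))
    stop("unknown stiffness_mode: ", cfg$stiffness_mode)
  if (!cfg$dominant_side %in% c("right", "left"))
    stop("dominant_side must be 'right' or 'left'")
  stopifnot(cfg$threshold > 0, cfg$cutoff > 0, cfg$filter_order >= 2,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$session_correlation >= 0, cfg$session_correlation <= 1)
  invisible(cfg)
}

#' Write / read a configuration as YAML
#' @param cfg a [dvj_config()]
#' @param path file path
#' @return `config_read` returns the validated `dvj_config`
#' @export
config_write <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  do.call(dvj_config, yaml::read_yaml(path))
}

# Draw one subject's session-level condition parameters: group mean per
# session plus a between-subject deviation correlated across sessions
# (shared subject effect), resampled if the draw is kinematically
# infeasible.
sample_subject_params <- function(ref, rho, vars, max_tries = 20) {
  for (try in seq_len(max_tries)) {
    b <- rnorm(length(vars))
    e0 <- rnorm(length(vars))
    e1 <- rnorm(length(vars))
    z0 <- sqrt(rho) * b + sqrt(1 - rho) * e0
    z1 <- sqrt(rho) * b + sqrt(1 - rho) * e1
    idx <- match(vars, ref$variable)
    v0 <- ref$mean_0h[idx] + ref$sd_0h[idx] * z0
    v1 <- ref$mean_48h[idx] + ref$sd_48h[idx] * z1
    names(v0) <- names(v1) <- vars
    ok <- function(v) {
      v["knee_flexion_peak_landing_deg"] > v["knee_flexion_ic_deg"] + 2 &&
        v["hip_flexion_peak_landing_deg"] > v["hip_flexion_ic_deg"] + 2 &&
        v["pelvis_tilt_peak_landing_deg"] > v["pelvis_tilt_ic_deg"] &&
        v["landing_duration_ms"] > 60 && v["propulsion_duration_ms"] > 60 &&
        v["jump_height_cm"] > 5
    }
    if (ok(v0) && ok(v1)) return(list(baseline = v0, damaged48h = v1))
  }
  stop("could not draw feasible subject parameters in ", max_tries, " tries")
}

params_from_values <- function(v, seed) {
  condition_params(
    drop_height = 0.30,
    pelvic_tilt_ic = v[["pelvis_tilt_ic_deg"]],
    peak_pelvic_tilt = v[["pelvis_tilt_peak_landing_deg"]],
    hip_flexion_ic = v[["hip_flexion_ic_deg"]],
    peak_hip_flexion = v[["hip_flexion_peak_landing_deg"]],
    knee_flexion_ic = v[["knee_flexion_ic_deg"]],
    peak_knee_flexion = v[["knee_flexion_peak_landing_deg"]],
    ankle_ic = v[["ankle_angle_ic_deg"]],
    peak_ankle = v[["ankle_angle_peak_landing_deg"]],
    landing_duration = v[["landing_duration_ms"]],
    propulsion_duration = v[["propulsion_duration_ms"]],
    jump_height = v[["jump_height_cm"]],
    seed = seed
  )
}

STUDY_PARAM_VARS <- c(
  "pelvis_tilt_ic_deg", "pelvis_tilt_peak_landing_deg",
  "hip_flexion_ic_deg", "hip_flexion_peak_landing_deg",
  "knee_flexion_ic_deg", "knee_flexion_peak_landing_deg",
  "ankle_angle_ic_deg", "ankle_angle_peak_landing_deg",
  "landing_duration_ms", "propulsion_duration_ms", "jump_height_cm"
)

#' Run a full synthetic pre/post study through the pipeline
#'
#' Generates a cohort (subjects sampled from the study population, each
#' with session-level condition parameters drawn around the baseline and
#' 48-h-post group means with a shared-subject correlation across
#' sessions), analyzes `trials_per_session` trials per subject and session
#' through the full pipeline, averages them, and compares sessions with
#' paired t-tests and percent changes per variable.
#'
#' @param n_subjects cohort size
#' @param trials_per_session DVJ trials analyzed per subject and session
#' @param seed study seed (drives subject sampling and trial noise)
#' @param config a [dvj_config()]
#' @param reference reference table, defaults to [dvj_reference_measures()]
#' @return list of class `dvj_study`: `metrics` (one row per subject and
#'   session, trial-averaged), `comparison` (per-variable pre/post mean,
#'   SD, t, p, percent change), `config`, `seed`
#' @export
run_study <- function(n_subjects = 13, trials_per_session = 3, seed = 1L,
                      config = dvj_config(),
                      reference = dvj_reference_measures()) {
  validate_config(config)
  rho <- config$session_correlation
  run_with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_subjects)) {
      subj <- subject_spec(mass = max(rnorm(1, 78.9, 8.5), 50),
                          height = max(rnorm(1, 1.811, 0.063), 1.5))
      static <- generate_static_trial(subj, seed = seed + 1000L + i)
      # redraw subject parameters when a draw is dynamically infeasible for
      # the generator (only successful trials enter the analysis)
      sp <- NULL
      for (try in 1:20) {
        cand <- sample_subject_params(reference, rho, STUDY_PARAM_VARS)
        feasible <- tryCatch({
          for (session in c("baseline", "damaged48h"))
            generate_dvj_trial(subj, params_from_values(cand[[session]], 1L))
          TRUE
        }, error = function(e) {
          if (grepl("infeasible", conditionMessage(e))) FALSE else stop(e)
        })
        if (feasible) { sp <- cand; break }
      }
      if (is.null(sp))
        stop("could not draw dynamically feasible parameters for subject ", i)
      for (session in c("baseline", "damaged48h")) {
        trial_metrics <- list()
        for (k in seq_len(trials_per_session)) {
          pr <- params_from_values(sp[[session]],
                                   seed = seed + 17L * i + 1000L * k +
                                     (session == "damaged48h") * 100000L)
          trial <- generate_dvj_trial(subj, pr)
          res <- tryCatch(analyze_trial(trial, static, config),
                          error = function(e) {
                            warning("trial skipped (subject ", i, ", ",
                                    session, ", trial ", k, "): ",
                                    conditionMessage(e))
                            NULL
                          })
          if (!is.null(res)) trial_metrics[[length(trial_metrics) + 1]] <-
              res$metrics
        }
        if (length(trial_metrics) == 0)
          stop("no successful trial for subject ", i, ", session ", session)
        avg <- average_trials(trial_metrics)
        rows[[length(rows) + 1]] <- cbind(
          data.frame(subject = i, session = session), avg)
      }
    }
    metrics <- do.call(rbind, rows)
    comparison <- compare_sessions(metrics, alpha = config$alpha)
    structure(list(metrics = metrics, comparison = comparison,
                   config = config, seed = seed),
              class = "dvj_study")
  })
}

# Per-variable paired pre/post comparison of a subject x session metrics
# table.
compare_sessions <- function(metrics, alpha = 0.05) {
  vars <- setdiff(names(metrics), c("subject", "session"))
  pre <- metrics[metrics$session == "baseline", ]
  post <- metrics[metrics$session == "damaged48h", ]
  pre <- pre[order(pre$subject), ]
  post <- post[order(post$subject), ]
  do.call(rbind, lapply(vars, function(v) {
    tt <- paired_t(pre[[v]], post[[v]])
    data.frame(
      variable = v,
      mean_pre = mean(pre[[v]]), sd_pre = sd(pre[[v]]),
      mean_post = mean(post[[v]]), sd_post = sd(post[[v]]),
      t = tt$t, p = tt$p,
      pct_change = percent_change(mean(pre[[v]]), mean(post[[v]])),
      significant = tt$p < alpha,
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.dvj_study <- function(x, ...) {
  cat(sprintf("<dvj_study> %d subjects, seed %d\n",
              length(unique(x$metrics$subject)), x$seed))
  cmp <- x$comparison
  cmp[, c("mean_pre", "mean_post", "pct_change")] <-
    round(cmp[, c("mean_pre", "mean_post", "pct_change")], 2)
  cmp$p <- signif(cmp$p, 3)
  print(cmp[, c("variable", "mean_pre", "mean_post", "pct_change", "p",
                "significant")], row.names = FALSE)
  invisible(x)
}

#' Write a study report
#'
#' Emits the per-subject metrics table and the session comparison as tidy
#' CSVs plus a human-readable text table, with the configuration and seed
#' logged alongside.
#'
#' @param study a [run_study()] result
#' @param out_dir output directory
#' @return invisibly, the written file paths
#' @export
write_study_report <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(out_dir, "metrics_by_subject.csv")
  p2 <- file.path(out_dir, "session_comparison.csv")
  p3 <- file.path(out_dir, "report.txt")
  p4 <- file.path(out_dir, "config.yaml")
  utils::write.csv(study$metrics, p1, row.names = FALSE)
  utils::write.csv(study$comparison, p2, row.names = FALSE)
  con <- file(p3, "w"); on.exit(close(con))
  writeLines(utils::capture.output(print(study)), con)
  config_write(study$config, p4)
  invisible(c(p1, p2, p3, p4))
}

#' Metric-level cohort power simulation
#'
#' Simulates repeated pre/post studies at the metric level: per replicate,
#' subject values for each variable are drawn from normal distributions
#' with the two sessions' group means and SDs and a shared-subject
#' correlation across sessions, then compared with a paired t-test. Returns
#' the per-variable rejection proportion — the power of the study design
#' under the tabulated session effects.
#'
#' @param n_subjects subjects per replicate
#' @param n_reps number of simulated studies
#' @param seed simulation seed
#' @param variables which reference variables to simulate (default: all
#'   with a reported significant difference)
#' @param rho within-subject correlation across sessions
#' @param alpha significance level
#' @param reference reference table, defaults to [dvj_reference_measures()]
#' @return data frame with `variable` and `power`
#' @export
simulate_study_power <- function(n_subjects = 13, n_reps = 100, seed = 1L,
                                 variables = NULL, rho = 0.8, alpha = 0.05,
                                 reference = dvj_reference_measures()) {
  if (is.null(variables))
    variables <- reference$variable[reference$significant]
  run_with_seed(seed, {
    out <- lapply(variables, function(v) {
      i <- match(v, reference$variable)
      if (is.na(i)) stop("unknown reference variable: ", v)
      set.seed(seed + 7919L * i)   # per-variable stream
      rej <- vapply(seq_len(n_reps), function(r) {
        b <- rnorm(n_subjects)
        pre <- reference$mean_0h[i] + reference$sd_0h[i] *
          (sqrt(rho) * b + sqrt(1 - rho) * rnorm(n_subjects))
        post <- reference$mean_48h[i] + reference$sd_48h[i] *
          (sqrt(rho) * b + sqrt(1 - rho) * rnorm(n_subjects))
        paired_t(pre, post)$p < alpha
      }, logical(1))
      data.frame(variable = v, power = mean(rej), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
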
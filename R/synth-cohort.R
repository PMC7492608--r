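#' Simulate one subject of a synthetic cohort
#'
#' Draws the subject's true PMBR-error coupling from the group's truncated
#' Gaussian (truncated at zero so the group's correlation sign is
#' preserved), simulates the error series, programs the 12 block PMBR
#' values against the realized block errors, and generates the EEG epochs,
#' ball tracks, per-block joint-velocity matrices and head-acceleration
#' traces. Uses the caller's RNG stream.
#'
#' @param config a [cohort_config()]
#' @param group `"increaser"` (negative coupling) or `"decreaser"`
#' @param subject_id integer id
#' @param geometry a [table_geometry()]
#' @param calibration optional precomputed [pmbr_burst_calibration()]
#' @return a list of class `pmbr_subject`; see Details
#' @details The returned list carries `errors` (signed degrees),
#' `block_pmbr_true`, `true_corr`, `eeg` (samples x trials), `track`
#' (compact arrays; see [subject_track()]), `kinematics` (list of
#' samples x joints matrices, one per block), `head_accel`
#' (samples x trials), `events` (trial/set/block and programmed onset), and
#' `complexity_target` (per block).
#' @export
generate_subject <- function(config, group, subject_id,
                             geometry = table_geometry(),
                             calibration = NULL) {
  gp <- config$groups[[group]]
  if (is.null(gp)) stop_pmbr("unknown group `", group, "`")
  seg <- segment_blocks(config$n_trials, config$set_size, config$block_size)

  # truncated Gaussian: resample until the coupling sign matches the group
  sgn <- if (gp$coupling$corr_mean < 0) -1 else 1
  repeat {
    true_corr <- stats::rnorm(1, gp$coupling$corr_mean, gp$coupling$corr_sd)
    if (sign(true_corr) == sgn && abs(true_corr) < 1) break
  }

  errors <- generate_error_series(gp$error_curve, config$n_trials)
  block_err <- tapply(abs(errors), seg$block, mean)
  block_pmbr <- program_block_pmbr(true_corr, as.numeric(block_err),
                                   config$pmbr_scale, config$pmbr_base)

  if (is.null(calibration))
    calibration <- pmbr_burst_calibration(sfreq = config$sfreq_eeg,
                                          trial_duration = config$trial_duration,
                                          offset_time = config$offset_time,
                                          snr = config$eeg_snr)
  amps <- vapply(block_pmbr[seg$block], burst_amp_for_target, numeric(1),
                 calibration = calibration)
  eeg <- synth_eeg_matrix(amps, config$trial_duration, config$offset_time,
                          config$sfreq_eeg, config$eeg_snr)

  tr0 <- generate_ball_track(0, config$offset_time, geometry,
                             config$sfreq_track)
  m <- nrow(tr0)
  cue <- array(NA_real_, c(m, 2, config$n_trials))
  target <- array(NA_real_, c(m, 2, config$n_trials))
  for (i in seq_len(config$n_trials)) {
    tr <- generate_ball_track(errors[i], config$offset_time, geometry,
                              config$sfreq_track)
    cue[, , i] <- cbind(tr$cue_x_mm, tr$cue_y_mm)
    target[, , i] <- cbind(tr$target_x_mm, tr$target_y_mm)
  }

  cx <- gp$complexity
  c_target <- seq(cx$initial_C, cx$final_C, length.out = config$n_blocks)
  kin <- lapply(c_target, function(C)
    generate_joint_velocities(C, config$n_joints, config$kin_samples_per_block))

  accel <- generate_head_accel(config$n_trials, config$trial_duration,
                               config$offset_time, config$sfreq_track)

  structure(list(
    subject = subject_id, group = group, true_corr = true_corr,
    errors = errors, block_pmbr_true = as.numeric(block_pmbr),
    eeg = eeg,
    track = list(time = tr0$time_s, cue = cue, target = target),
    kinematics = kin, head_accel = accel,
    complexity_target = c_target,
    events = tibble::tibble(trial = seg$trial, set = seg$set,
                            block = seg$block,
                            ball_onset_time_s = config$offset_time),
    geometry = geometry
  ), class = "pmbr_subject")
}

#' Rebuild the per-trial ball-track data frame of a subject
#'
#' @param subject a `pmbr_subject`
#' @param trial trial index
#' @return track data frame as produced by [generate_ball_track()]
#' @export
subject_track <- function(subject, trial) {
  data.frame(time_s = subject$track$time,
             cue_x_mm = subject$track$cue[, 1, trial],
             cue_y_mm = subject$track$cue[, 2, trial],
             target_x_mm = subject$track$target[, 1, trial],
             target_y_mm = subject$track$target[, 2, trial])
}

#' Simulate a full synthetic cohort
#'
#' Generates every subject (the first `n_negative_coupling` subjects belong
#' to the negative-coupling increaser group) plus the ground-truth table
#' used by parameter-recovery tests. Fully reproducible from
#' `config$seed`; when `out_dir` is given the cohort is also written to
#' disk via [write_cohort()].
#'
#' @param config a [cohort_config()]
#' @param out_dir optional output directory
#' @param geometry a [table_geometry()]
#' @return a list of class `pmbr_cohort` with `config`, `truth` (tibble)
#'   and `subjects` (list of `pmbr_subject`)
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL,
                            geometry = table_geometry()) {
  calibration <- pmbr_burst_calibration(sfreq = config$sfreq_eeg,
                                        trial_duration = config$trial_duration,
                                        offset_time = config$offset_time,
                                        snr = config$eeg_snr)
  groups <- rep(c("increaser", "decreaser"),
                c(config$n_negative_coupling,
                  config$n_subjects - config$n_negative_coupling))
  subjects <- with_private_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(i)
      generate_subject(config, groups[i], i, geometry, calibration))
  })
  truth <- do.call(rbind, lapply(subjects, function(s) {
    ec <- config$groups[[s$group]]$error_curve
    tibble::tibble(subject = s$subject, group = s$group,
                   true_corr = s$true_corr,
                   initial_bias = ec$initial_bias,
                   plateau_bias = ec$plateau_bias,
                   initial_sd = ec$initial_sd, plateau_sd = ec$plateau_sd,
                   decay_constant = ec$decay_constant, ar1_rho = ec$ar1_rho,
                   block = list(seq_len(config$n_blocks)),
                   pmbr_true = list(s$block_pmbr_true),
                   complexity_target = list(s$complexity_target))
  }))
  cohort <- structure(list(config = config, truth = truth,
                           subjects = subjects, geometry = geometry),
                      class = "pmbr_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.pmbr_cohort <- function(x, ...) {
  cat("<pmbr_cohort>\n")
  print(x$config)
  invisible(x)
}
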
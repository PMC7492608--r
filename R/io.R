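# Disk interface for synthetic cohorts: one directory per subject with
# eeg.edf (concatenated 6-s epochs, channel "C3"), events.csv, tracks.csv,
# head_accel.csv and kinematics-block-NN.csv, plus truth.csv and
# config.yaml at the cohort root.

#' Write a synthetic cohort to disk
#'
#' @param cohort a `pmbr_cohort` from [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_pmbr("cannot create output directory ", dir)
  cfg <- unclass(cohort$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  truth <- cohort$truth
  flat <- truth[, c("subject", "group", "true_corr", "initial_bias",
                    "plateau_bias", "initial_sd", "plateau_sd",
                    "decay_constant", "ar1_rho")]
  pm <- do.call(rbind, truth$pmbr_true)
  colnames(pm) <- sprintf("pmbr_true_b%02d", seq_len(ncol(pm)))
  cx <- do.call(rbind, truth$complexity_target)
  colnames(cx) <- sprintf("complexity_b%02d", seq_len(ncol(cx)))
  utils::write.csv(cbind(flat, pm, cx), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  for (s in cohort$subjects) {
    sd_ <- file.path(dir, sprintf("subject-%02d", s$subject))
    dir.create(sd_, showWarnings = FALSE)
    write_edf(file.path(sd_, "eeg.edf"), as.vector(s$eeg),
              cohort$config$sfreq_eeg)
    utils::write.csv(s$events, file.path(sd_, "events.csv"),
                     row.names = FALSE)
    n_trials <- ncol(s$eeg)
    tracks <- do.call(rbind, lapply(seq_len(n_trials), function(i)
      cbind(trial = i, subject_track(s, i))))
    utils::write.csv(tracks, file.path(sd_, "tracks.csv"), row.names = FALSE)
    acc <- as.data.frame(s$head_accel)
    names(acc) <- sprintf("trial_%03d", seq_len(ncol(acc)))
    utils::write.csv(acc, file.path(sd_, "head_accel.csv"),
                     row.names = FALSE)
    for (b in seq_along(s$kinematics)) {
      kin <- as.data.frame(s$kinematics[[b]])
      names(kin) <- sprintf("joint_%02d", seq_len(ncol(kin)))
      utils::write.csv(kin, file.path(sd_, sprintf("kinematics-block-%02d.csv", b)),
                       row.names = FALSE)
    }
    utils::write.csv(data.frame(trial = seq_len(n_trials),
                                error_deg = s$errors),
                     file.path(sd_, "errors.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a synthetic cohort from disk
#'
#' Inverse of [write_cohort()]; reconstructs the epoched EEG from the
#' concatenated EDF using the epoch length in the config.
#'
#' @param dir cohort directory
#' @return a `pmbr_cohort`
#' @export
read_cohort <- function(dir) {
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  keep <- setdiff(names(formals(cohort_config)), "groups")
  cfg <- do.call(cohort_config, c(cfgl[intersect(names(cfgl), keep)],
                                  list(groups = cfgl$groups)))
  truth_flat <- utils::read.csv(file.path(dir, "truth.csv"))
  pm_cols <- grep("^pmbr_true_b", names(truth_flat))
  cx_cols <- grep("^complexity_b", names(truth_flat))
  truth <- tibble::as_tibble(truth_flat[, -c(pm_cols, cx_cols)])
  truth$pmbr_true <- lapply(seq_len(nrow(truth_flat)), function(i)
    as.numeric(truth_flat[i, pm_cols]))
  truth$complexity_target <- lapply(seq_len(nrow(truth_flat)), function(i)
    as.numeric(truth_flat[i, cx_cols]))

  n_samp <- round(cfg$trial_duration * cfg$sfreq_eeg)
  subjects <- lapply(truth$subject, function(i) {
    sd_ <- file.path(dir, sprintf("subject-%02d", i))
    edf <- read_edf(file.path(sd_, "eeg.edf"))
    eeg <- matrix(edf$channels[[1]], nrow = n_samp)
    events <- tibble::as_tibble(utils::read.csv(file.path(sd_, "events.csv")))
    tracks <- utils::read.csv(file.path(sd_, "tracks.csv"))
    m <- sum(tracks$trial == 1)
    n_trials <- max(tracks$trial)
    cue <- array(NA_real_, c(m, 2, n_trials))
    target <- array(NA_real_, c(m, 2, n_trials))
    for (tr in seq_len(n_trials)) {
      sub <- tracks[tracks$trial == tr, ]
      cue[, , tr] <- cbind(sub$cue_x_mm, sub$cue_y_mm)
      target[, , tr] <- cbind(sub$target_x_mm, sub$target_y_mm)
    }
    acc <- as.matrix(utils::read.csv(file.path(sd_, "head_accel.csv")))
    kin_files <- sort(list.files(sd_, "^kinematics-block-", full.names = TRUE))
    kin <- lapply(kin_files, function(f) as.matrix(utils::read.csv(f)))
    errs <- utils::read.csv(file.path(sd_, "errors.csv"))
    structure(list(
      subject = i, group = truth$group[truth$subject == i],
      true_corr = truth$true_corr[truth$subject == i],
      errors = errs$error_deg,
      block_pmbr_true = truth$pmbr_true[[which(truth$subject == i)]],
      eeg = eeg,
      track = list(time = tracks$time_s[tracks$trial == 1],
                   cue = cue, target = target),
      kinematics = kin, head_accel = unname(acc),
      complexity_target = truth$complexity_target[[which(truth$subject == i)]],
      events = events, geometry = table_geometry()
    ), class = "pmbr_subject")
  })
  structure(list(config = cfg, truth = truth, subjects = subjects,
                 geometry = table_geometry()),
            class = "pmbr_cohort")
}
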
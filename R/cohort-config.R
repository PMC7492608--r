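#' Configuration for a synthetic motor-learning cohort
#'
#' Builds the full parameter set of the synthetic-cohort generator. The
#' defaults describe a 30-subject cohort performing 300 self-paced shots
#' (6 sets of 50 trials, analysed as 12 blocks of 25), with two latent
#' learner groups distinguished by the sign of the coupling between their
#' block-averaged post-movement beta rebound (PMBR) and their block mean
#' absolute directional error:
#'
#' * `increaser` — negative PMBR–error coupling (subject-level true Pearson
#'   r drawn from a Gaussian with mean -0.40, SD 0.26, truncated at 0), the
#'   profile associated with error-based adaptation; 16 of 30 subjects.
#' * `decreaser` — positive coupling (mean +0.47, SD 0.17, truncated at 0),
#'   the profile associated with reward-based learning; 14 of 30 subjects.
#'
#' Error-curve defaults are calibrated (folded-normal closed form plus a
#' Monte-Carlo correction for the small bias of the realized learning-rate
#' ratio) so the expected group learning rates are 0.48 (increasers) and
#' 0.60 (decreasers),
#' and so that decreasers show larger initial variability, a faster decay of
#' that variability, larger early trial-to-trial changes and a larger decay
#' of the lag-1 error autocorrelation, while increasers use more movement
#' degrees of freedom (higher manipulative complexity) throughout.
#'
#' @param n_subjects number of subjects (default 30)
#' @param n_negative_coupling number of subjects in the negative-coupling
#'   (increaser) group (default 16)
#' @param n_trials trials per subject (default 300)
#' @param set_size trials per experimental set (default 50)
#' @param block_size trials per analysis block (default 25)
#' @param sfreq_eeg EEG sampling rate in Hz (default 256)
#' @param sfreq_track ball-tracking sampling rate in Hz (default 200)
#' @param trial_duration EEG epoch length in seconds (default 6)
#' @param offset_time programmed movement offset within the epoch, seconds
#'   (default 3)
#' @param pmbr_base baseline programmed block PMBR level, percent change
#'   (default 40; chosen above the floor of the peak-search extraction so
#'   that programmed excursions stay in the responsive range of the
#'   burst-amplitude calibration)
#' @param pmbr_scale scale of programmed block-PMBR excursions, percent
#'   change units (default 8)
#' @param eeg_snr ratio scaling the beta-band signal against the broadband
#'   1/f background (default 1; larger is cleaner)
#' @param n_joints number of joints in the synthetic velocity matrices
#'   (default 20)
#' @param kin_samples_per_block velocity samples per block (default 1000)
#' @param groups per-group parameter lists; see Details. Partial overrides
#'   are merged over the defaults.
#' @param seed integer seed; the whole cohort is reproducible from it
#'
#' @details Each group entry carries `error_curve` (`initial_bias`,
#' `plateau_bias`, `initial_sd`, `plateau_sd` in degrees; `decay_constant`
#' in trials; `ar1_rho` in \[-1, 1\]), `coupling` (`corr_mean`, `corr_sd` of
#' the subject-level true PMBR–error correlation), and `complexity`
#' (`initial_C`, `final_C` in \[0, 1\]).
#'
#' @return an object of class `cohort_config` (a validated list)
#' @export
cohort_config <- function(n_subjects = 30,
                          n_negative_coupling = 16,
                          n_trials = 300,
                          set_size = 50,
                          block_size = 25,
                          sfreq_eeg = 256,
                          sfreq_track = 200,
                          trial_duration = 6,
                          offset_time = 3,
                          pmbr_base = 40,
                          pmbr_scale = 8,
                          eeg_snr = 1,
                          n_joints = 20,
                          kin_samples_per_block = 1000,
                          groups = list(),
                          seed = 1L) {
  defaults <- list(
    increaser = list(
      error_curve = list(initial_bias = 7.02, plateau_bias = 2,
                         initial_sd = 5, plateau_sd = 3.5,
                         decay_constant = 50, ar1_rho = 0.25),
      coupling   = list(corr_mean = -0.40, corr_sd = 0.26),
      complexity = list(initial_C = 0.55, final_C = 0.70)
    ),
    decreaser = list(
      error_curve = list(initial_bias = 10.56, plateau_bias = 1.5,
                         initial_sd = 9, plateau_sd = 3.5,
                         decay_constant = 20, ar1_rho = 0.30),
      coupling   = list(corr_mean = 0.47, corr_sd = 0.17),
      complexity = list(initial_C = 0.45, final_C = 0.62)
    )
  )
  for (g in names(groups)) {
    if (!g %in% names(defaults))
      stop_pmbr("unknown group `", g, "` (expected increaser/decreaser)")
    for (part in names(groups[[g]]))
      defaults[[g]][[part]][names(groups[[g]][[part]])] <- groups[[g]][[part]]
  }

  cfg <- list(
    n_subjects = assert_count(n_subjects, "n_subjects"),
    n_negative_coupling = assert_count(n_negative_coupling,
                                       "n_negative_coupling", min = 0L),
    n_trials = assert_count(n_trials, "n_trials", min = 2L),
    set_size = assert_count(set_size, "set_size"),
    block_size = assert_count(block_size, "block_size"),
    sfreq_eeg = assert_finite_scalar(sfreq_eeg, "sfreq_eeg"),
    sfreq_track = assert_finite_scalar(sfreq_track, "sfreq_track"),
    trial_duration = assert_finite_scalar(trial_duration, "trial_duration"),
    offset_time = assert_finite_scalar(offset_time, "offset_time"),
    pmbr_base = assert_finite_scalar(pmbr_base, "pmbr_base"),
    pmbr_scale = assert_finite_scalar(pmbr_scale, "pmbr_scale"),
    eeg_snr = assert_finite_scalar(eeg_snr, "eeg_snr"),
    n_joints = assert_count(n_joints, "n_joints", min = 2L),
    kin_samples_per_block = assert_count(kin_samples_per_block,
                                         "kin_samples_per_block"),
    groups = defaults,
    seed = assert_count(seed, "seed", min = 0L)
  )

  if (cfg$n_negative_coupling > cfg$n_subjects)
    stop_pmbr("n_negative_coupling must not exceed n_subjects")
  if (cfg$n_trials %% cfg$block_size != 0)
    stop_pmbr("n_trials must be divisible by block_size")
  if (cfg$set_size %% cfg$block_size != 0)
    stop_pmbr("set_size must be divisible by block_size")
  for (g in names(cfg$groups)) {
    ec <- cfg$groups[[g]]$error_curve
    if (!all(vapply(ec, is.finite, logical(1))))
      stop_pmbr("non-finite error-curve parameter in group `", g, "`")
    if (ec$initial_sd <= 0 || ec$plateau_sd <= 0)
      stop_pmbr("error-curve SDs must be > 0 in group `", g, "`")
    if (ec$decay_constant <= 0)
      stop_pmbr("decay_constant must be > 0 in group `", g, "`")
    if (abs(ec$ar1_rho) > 1)
      stop_pmbr("ar1_rho must lie in [-1, 1] in group `", g, "`")
    cc <- cfg$groups[[g]]$complexity
    if (cc$initial_C < 0 || cc$initial_C > 1 || cc$final_C < 0 || cc$final_C > 1)
      stop_pmbr("complexity targets must lie in [0, 1] in group `", g, "`")
    cp <- cfg$groups[[g]]$coupling
    if (abs(cp$corr_mean) > 1 || cp$corr_sd <= 0)
      stop_pmbr("invalid coupling parameters in group `", g, "`")
  }
  if (cfg$offset_time + 2 > cfg$trial_duration)
    stop_pmbr("trial_duration must cover offset_time + 2 s")

  cfg$n_blocks <- cfg$n_trials %/% cfg$block_size
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects (%d increaser / %d decreaser), %d trials in %d blocks of %d\n",
              x$n_subjects, x$n_negative_coupling,
              x$n_subjects - x$n_negative_coupling,
              x$n_trials, x$n_blocks, x$block_size))
  cat(sprintf("  EEG %g Hz, tracking %g Hz, epoch %g s (offset %g s), seed %d\n",
              x$sfreq_eeg, x$sfreq_track, x$trial_duration, x$offset_time,
              x$seed))
  invisible(x)
}
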
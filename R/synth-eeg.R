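# Synthetic single-channel EEG: 1/f background + baseline beta-band activity
# with a movement-related desynchronization, plus a Gaussian-envelope 20 Hz
# burst after movement offset whose amplitude encodes the programmed PMBR.

# amplitude scale constants (arbitrary "uV-like" units; the block-relative
# log normalization requires ln(power) > 0, which these scales guarantee)
.EEG_BETA_SD <- 20
.EEG_PINK_SD <- 40

# 1/f-shaped noise via frequency-domain amplitude shaping
pink_noise <- function(n, sfreq) {
  N <- stats::nextn(n, 2)
  f <- c(1, seq_len(N - 1))
  f <- pmin(f, N - f + 1)              # two-sided frequency index
  shape <- 1 / sqrt(f)
  x <- Re(stats::fft(stats::fft(stats::rnorm(N)) * shape, inverse = TRUE)) / N
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# Gaussian-band-limited noise centred at `f0` (Hz) with spectral SD `fsd`
narrowband_noise <- function(n, sfreq, f0, fsd) {
  N <- stats::nextn(n, 2)
  fr <- (seq_len(N) - 1) * sfreq / N
  fr <- pmin(fr, sfreq - fr)
  shape <- exp(-(fr - f0)^2 / (2 * fsd^2))
  x <- Re(stats::fft(stats::fft(stats::rnorm(N)) * shape, inverse = TRUE)) / N
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

#' Simulate one trial of single-channel EEG
#'
#' The trace is the sum of a 1/f background, baseline beta-band (13-30 Hz,
#' centred 20 Hz) activity attenuated during the movement period
#' (event-related desynchronization), and a Gaussian-envelope 20 Hz burst
#' (envelope SD 150 ms) whose centre falls 0.35-0.75 s after `offset_time`.
#' The burst amplitude is an increasing function of `pmbr_target`, mapped
#' through the calibration sweep of [pmbr_burst_calibration()] so that the
#' pipeline-extracted PMBR is monotone in (and approximately equal to) the
#' target.
#'
#' @param pmbr_target programmed PMBR for this trial, percent change; 0
#'   produces no burst
#' @param trial_duration epoch length in s (must cover `offset_time` + 2 s)
#' @param offset_time movement offset within the epoch, s
#' @param sfreq sampling rate in Hz
#' @param snr ratio scaling the broadband background down (higher = cleaner)
#' @param calibration optional result of [pmbr_burst_calibration()]; computed
#'   (and cached) from the other arguments when NULL
#' @return numeric vector of `trial_duration * sfreq` samples
#' @export
generate_trial_eeg <- function(pmbr_target, trial_duration = 6,
                               offset_time = 3, sfreq = 256, snr = 1,
                               calibration = NULL) {
  if (trial_duration <= 0 || sfreq <= 0)
    stop_pmbr("trial_duration and sfreq must be positive")
  if (offset_time + 2 > trial_duration)
    stop_pmbr("epoch must cover offset_time + 2 s")
  if (is.null(calibration))
    calibration <- pmbr_burst_calibration(sfreq = sfreq,
                                          trial_duration = trial_duration,
                                          offset_time = offset_time,
                                          snr = snr)
  amp <- burst_amp_for_target(pmbr_target, calibration)
  synth_eeg_trace(amp, trial_duration, offset_time, sfreq, snr)
}

# raw trace for a given burst amplitude (internal; used by the calibration)
synth_eeg_trace <- function(burst_amp, trial_duration, offset_time, sfreq,
                            snr, burst_freq = 20, burst_env_sd = 0.15) {
  n <- round(trial_duration * sfreq)
  t <- (seq_len(n) - 1) / sfreq
  bg <- .EEG_PINK_SD / snr * pink_noise(n, sfreq)
  # movement-period beta desynchronization (Gaussian dip ending at offset)
  erd <- 1 - 0.35 * exp(-(t - (offset_time - 0.5))^2 / (2 * 0.3^2))
  beta <- .EEG_BETA_SD * narrowband_noise(n, sfreq, 20, 4) * erd
  x <- bg + beta
  if (burst_amp > 0) {
    latency <- stats::runif(1, 0.35, 0.75)
    tc <- offset_time + latency
    phi <- stats::runif(1, 0, 2 * pi)
    x <- x + burst_amp * exp(-(t - tc)^2 / (2 * burst_env_sd^2)) *
      cos(2 * pi * burst_freq * t + phi)
  }
  x
}

# batched trace synthesis for a whole subject (one FFT pass per noise
# component instead of one per trial); statistically identical to repeated
# synth_eeg_trace() calls
synth_eeg_matrix <- function(burst_amps, trial_duration, offset_time, sfreq,
                             snr, burst_freq = 20, burst_env_sd = 0.15) {
  n <- round(trial_duration * sfreq)
  nt <- length(burst_amps)
  t <- (seq_len(n) - 1) / sfreq
  N <- stats::nextn(n, 2)
  shaped_noise <- function(shape) {
    W <- stats::mvfft(matrix(stats::rnorm(N * nt), N, nt))
    x <- Re(stats::mvfft(W * shape, inverse = TRUE))[seq_len(n), , drop = FALSE]
    sweep(x, 2, apply(x, 2, stats::sd), `/`)
  }
  f <- c(1, seq_len(N - 1)); f <- pmin(f, N - f + 1)
  pink <- shaped_noise(1 / sqrt(f))
  fr <- (seq_len(N) - 1) * sfreq / N; fr <- pmin(fr, sfreq - fr)
  beta <- shaped_noise(exp(-(fr - 20)^2 / (2 * 4^2)))
  erd <- 1 - 0.35 * exp(-(t - (offset_time - 0.5))^2 / (2 * 0.3^2))
  x <- .EEG_PINK_SD / snr * pink + .EEG_BETA_SD * beta * erd
  tc <- offset_time + stats::runif(nt, 0.35, 0.75)
  phi <- stats::runif(nt, 0, 2 * pi)
  env <- exp(-outer(t, tc, `-`)^2 / (2 * burst_env_sd^2))
  osc <- cos(outer(2 * pi * burst_freq * t, phi, `+`))
  x + env * osc * rep(burst_amps, each = n)
}

.calib_cache <- new.env(parent = emptyenv())

#' Burst-amplitude calibration sweep
#'
#' Establishes, once per parameter set, the mapping from burst amplitude to
#' the pipeline-extracted PMBR (percent change): for each amplitude on a
#' grid, one block of trials is simulated and pushed through the actual
#' Morlet / block-normalization / peak-extraction path, and the mean
#' extracted PMBR recorded. The resulting lookup (made monotone by a
#' running maximum) is inverted by linear interpolation to choose burst
#' amplitudes for programmed targets. The sweep runs under a fixed private
#' RNG stream, so the mapping is a deterministic function of its parameters
#' and does not disturb the caller's RNG state; results are cached within
#' the session.
#'
#' @param sfreq,trial_duration,offset_time,snr as in [generate_trial_eeg()]
#' @param amps amplitude grid (trace units)
#' @param n_trials trials per calibration block (matching the analysis
#'   block size so the block normalization operates as in a real cohort)
#' @param n_blocks replicate blocks per amplitude (averaged)
#' @return object of class `pmbr_calibration`: tibble of `amp` and
#'   `pmbr_hat` plus the parameters as attributes
#' @export
pmbr_burst_calibration <- function(sfreq = 256, trial_duration = 6,
                                   offset_time = 3, snr = 1,
                                   amps = c(0, 5, 10, 20, 35, 55, 80, 110,
                                            150, 200, 260, 330, 420),
                                   n_trials = 25, n_blocks = 3) {
  key <- paste(sfreq, trial_duration, offset_time, snr,
               paste(amps, collapse = ","), n_trials, n_blocks, sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  pmbr_hat <- with_private_seed(992861, {
    vapply(amps, function(a) {
      mean(vapply(seq_len(n_blocks), function(b) {
        eeg <- vapply(seq_len(n_trials), function(i)
          synth_eeg_trace(a, trial_duration, offset_time, sfreq, snr),
          numeric(round(trial_duration * sfreq)))
        res <- analyze_subject_eeg(eeg, sfreq, rep(offset_time, n_trials),
                                   rep(1L, n_trials), freqs = 13:30,
                                   filter_band = NULL)
        mean(res$trials$pmbr_pct, na.rm = TRUE)
      }, numeric(1)))
    }, numeric(1))
  })
  out <- tibble::tibble(amp = amps, pmbr_hat = cummax(pmbr_hat))
  attr(out, "params") <- list(sfreq = sfreq, trial_duration = trial_duration,
                              offset_time = offset_time, snr = snr)
  class(out) <- c("pmbr_calibration", class(out))
  .calib_cache[[key]] <- out
  out
}

# invert the calibration: programmed target (%) -> burst amplitude
burst_amp_for_target <- function(target, calibration) {
  if (!is.finite(target) || target <= 0) return(0)
  if (target <= calibration$pmbr_hat[1]) return(0)
  stats::approx(calibration$pmbr_hat, calibration$amp, xout = target,
                rule = 2, ties = "ordered")$y
}
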
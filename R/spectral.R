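#' Windowed-sinc band-pass FIR design
#'
#' Hamming-windowed sinc band-pass kernel (odd length, symmetric, hence
#' linear phase; applied by centred convolution it is zero-phase).
#'
#' @param low,high band edges in Hz
#' @param sfreq sampling rate in Hz
#' @param n_taps odd kernel length (default 385, i.e. 1.5 s at 256 Hz;
#'   transition width ~2.2 Hz)
#' @return numeric vector of filter coefficients
#' @export
design_fir_bandpass <- function(low, high, sfreq, n_taps = 385) {
  assert_finite_scalar(low, "low"); assert_finite_scalar(high, "high")
  if (!(low > 0 && low < high && high < sfreq / 2))
    stop_pmbr("need 0 < low < high < Nyquist")
  n_taps <- assert_count(n_taps, "n_taps", min = 3L)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1L
  m <- (n_taps - 1) / 2
  k <- -m:m
  sinc <- function(fc) {
    out <- 2 * fc / sfreq * rep(1, length(k))
    nz <- k != 0
    out[nz] <- sin(2 * pi * fc / sfreq * k[nz]) / (pi * k[nz])
    out
  }
  h <- (sinc(high) - sinc(low)) * (0.54 + 0.46 * cos(pi * k / m))
  # unity gain at band centre
  fc <- sqrt(low * high)
  h / abs(sum(h * exp(-2i * pi * fc / sfreq * k)))
}

# centred FFT convolution of each column of `x` with symmetric kernel `h`
fft_filter <- function(x, h) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- (length(h) - 1) / 2
  N <- stats::nextn(n + length(h) - 1, 2)
  H <- stats::fft(c(h, numeric(N - length(h))))
  X <- stats::mvfft(rbind(x, matrix(0, N - n, ncol(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / N
  y[(m + 1):(m + n), , drop = FALSE]
}

#' Zero-phase band-pass filter
#'
#' Filters each column of `x` with a Hamming windowed-sinc band-pass via
#' centred FFT convolution. Length is preserved; the signal is zero-padded,
#' so the first/last half-kernel of samples carry edge roll-off (the trial
#' epochs analysed downstream keep their windows of interest away from the
#' edges).
#'
#' @param x numeric vector or matrix (samples x trials)
#' @param low,high band edges in Hz (defaults 5 and 35)
#' @param sfreq sampling rate in Hz
#' @param n_taps FIR length (see [design_fir_bandpass()])
#' @return filtered data, same shape as `x`
#' @export
bandpass <- function(x, low = 5, high = 35, sfreq = 256, n_taps = 385) {
  was_vec <- is.null(dim(x))
  if (!all(is.finite(x))) stop_pmbr("non-finite samples in input")
  h <- design_fir_bandpass(low, high, sfreq, n_taps)
  y <- fft_filter(as.matrix(x), h)
  if (was_vec) drop(y) else y
}

#' Morlet wavelet time-frequency power
#'
#' Convolves each trial (column) with complex Morlet wavelets at the given
#' frequencies and returns squared magnitude. The wavelet at frequency f has
#' temporal SD `n_cycles / (2 pi f)` and Gaussian envelope truncated at
#' 4 SD; the envelope is normalized to unit sum so a sinusoid of amplitude A
#' yields power ~ (A/2)^2 at its frequency. Samples within half a wavelet of
#' either epoch edge are flagged invalid.
#'
#' @param x numeric vector or matrix (samples x trials)
#' @param sfreq sampling rate in Hz
#' @param freqs analysis frequencies in Hz (default 5:35, 1 Hz steps)
#' @param n_cycles wavelet width in cycles (default 7)
#' @return list with `power` (array samples x freqs x trials), `valid`
#'   (logical matrix samples x freqs), `freqs`, `times`
#' @export
morlet_power <- function(x, sfreq, freqs = 5:35, n_cycles = 7) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!all(is.finite(x))) stop_pmbr("non-finite samples in input")
  sd_t <- n_cycles / (2 * pi * freqs)
  half <- ceiling(4 * sd_t * sfreq)
  if (max(2 * half + 1) > n)
    stop_pmbr("trace shorter than the widest wavelet support")
  N <- stats::nextn(n + max(2 * half + 1) - 1, 2)
  X <- stats::mvfft(rbind(x, matrix(0, N - n, ncol(x))))
  power <- array(NA_real_, c(n, length(freqs), ncol(x)))
  valid <- matrix(TRUE, n, length(freqs))
  for (j in seq_along(freqs)) {
    h <- half[j]
    t <- (-h:h) / sfreq
    env <- exp(-t^2 / (2 * sd_t[j]^2))
    w <- env / sum(env) * exp(2i * pi * freqs[j] * t)
    W <- stats::fft(c(w, complex(real = numeric(N - length(w)))))
    y <- stats::mvfft(X * W, inverse = TRUE) / N
    seg <- y[(h + 1):(h + n), , drop = FALSE]
    power[, j, ] <- Re(seg)^2 + Im(seg)^2
    valid[c(seq_len(h), (n - h + 1):n), j] <- FALSE
  }
  list(power = power, valid = valid, freqs = freqs,
       times = (seq_len(n) - 1) / sfreq)
}

#' Block-relative log-power normalization (percent change)
#'
#' Converts raw time-frequency power to percent change relative to the
#' block average, following the log-then-normalize reading: per frequency
#' row, `L = ln(P)` and `value = 100 * (L / mean_block(L) - 1)`, where
#' `mean_block` averages `L` over all valid samples of all trials assigned
#' to the block. The alternative order (average raw power within the block,
#' then take the log ratio) is available via `method = "log_ratio"`:
#' `value = 100 * (ln(P / mean_block(P)))`; the two agree to first order
#' for small fluctuations up to a scale factor.
#'
#' @param power array samples x freqs x trials of positive raw power
#' @param valid logical matrix samples x freqs (from [morlet_power()])
#' @param trial_block integer block index per trial
#' @param method `"log_then_norm"` (default, the literal reading) or
#'   `"log_ratio"`
#' @return array of normalized values, same shape as `power`; invalid
#'   samples are NA
#' @export
block_normalize <- function(power, valid, trial_block,
                            method = c("log_then_norm", "log_ratio")) {
  method <- match.arg(method)
  dp <- dim(power)
  if (length(dp) != 3) stop_pmbr("power must be a samples x freqs x trials array")
  if (length(trial_block) != dp[3])
    stop_pmbr("trial_block must have one entry per trial")
  out <- array(NA_real_, dp)
  n <- dp[1]
  inval <- which(!valid)                 # linear indices within one trial slab
  for (b in unique(trial_block)) {
    tr <- which(trial_block == b)
    P <- power[, , tr, drop = FALSE]
    if (anyNA(P) || min(P) <= 0)
      stop_pmbr("non-positive raw power in block ", b,
                " (upstream numerical fault)")
    L <- log(P)
    # per-frequency mean over valid samples of all trials in the block
    fmean <- function(A) rowSums(matrix(colSums(A * as.vector(valid)), dp[2])) /
      (colSums(valid) * length(tr))
    if (method == "log_then_norm") {
      m <- fmean(L)
      if (any(abs(m) < 1e-9))
        stop_pmbr("block-mean log power ~ 0; rescale input units")
      val <- L * rep(100 / m, each = n) - 100
    } else {
      val <- 100 * (L - rep(log(fmean(P)), each = n))
    }
    if (length(inval))
      val[as.vector(outer(inval, (seq_along(tr) - 1) * n * dp[2], `+`))] <- NA_real_
    out[, , tr] <- val
  }
  out
}

# mean over band rows (freqs within [band[1], band[2]]) of a samples x freqs
# slice; NA where any band row is invalid
band_average <- function(values, freqs, band) {
  cols <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(cols)) stop_pmbr("no analysis frequencies inside the band")
  rowMeans(values[, cols, drop = FALSE])
}

#' Extract the per-trial post-movement beta rebound
#'
#' Band-averages the normalized power over the beta band, searches the
#' 2-s window after movement offset for the peak, and returns the mean
#' over a 200-ms window centred on that peak (truncated at the search
#' window boundaries when the peak falls within half a window of an edge).
#' Ties in the peak are broken to the earliest sample.
#'
#' @param values normalized samples x freqs matrix for one trial (NA where
#'   invalid)
#' @param times sample times in seconds
#' @param freqs analysis frequencies in Hz
#' @param offset_time movement offset (s); the search window is
#'   `[offset_time, offset_time + search_window]`
#' @param band beta band limits in Hz (default `c(13, 30)`)
#' @param search_window length of the peak search window in s (default 2)
#' @param avg_window length of the averaging window in s (default 0.2)
#' @return list with `pmbr` (% change), `peak_time` (s, relative to
#'   offset), `usable`, `truncated`
#' @export
extract_pmbr <- function(values, times, freqs, offset_time,
                         band = c(13, 30), search_window = 2,
                         avg_window = 0.2) {
  bavg <- band_average(values, freqs, band)
  extract_pmbr_series(bavg, times, offset_time, search_window, avg_window)
}

# peak search + window mean on a precomputed band-averaged series
extract_pmbr_series <- function(bavg, times, offset_time, search_window = 2,
                                avg_window = 0.2) {
  in_search <- times >= offset_time & times <= offset_time + search_window
  if (!any(in_search) || times[length(times)] < offset_time + search_window)
    stop_pmbr("time axis does not cover the search window")
  seg <- bavg[in_search]
  if (anyNA(seg))
    return(list(pmbr = NA_real_, peak_time = NA_real_, usable = FALSE,
                truncated = FALSE))
  tseg <- times[in_search]
  ipk <- which.max(seg)                      # earliest tie wins
  tpk <- tseg[ipk]
  lo <- tpk - avg_window / 2
  hi <- tpk + avg_window / 2
  truncated <- lo < offset_time || hi > offset_time + search_window
  lo <- max(lo, offset_time)
  hi <- min(hi, offset_time + search_window)
  win <- tseg >= lo & tseg <= hi
  list(pmbr = mean(seg[win]), peak_time = tpk - offset_time,
       usable = TRUE, truncated = truncated)
}

#' Per-trial baseline beta power
#'
#' Mean band-averaged normalized power over a window before movement onset
#' (default: 500 ms ending 100 ms pre-onset), for baseline-difference
#' reporting between learner groups.
#'
#' @inheritParams extract_pmbr
#' @param onset_time movement onset in s
#' @param window_length baseline window length in s (default 0.5)
#' @param gap gap between window end and onset in s (default 0.1)
#' @return baseline beta power (% change), or NA if the window is not
#'   covered by valid samples
#' @export
baseline_beta <- function(values, times, freqs, onset_time,
                          band = c(13, 30), window_length = 0.5, gap = 0.1) {
  bavg <- band_average(values, freqs, band)
  baseline_beta_series(bavg, times, onset_time, window_length, gap)
}

baseline_beta_series <- function(bavg, times, onset_time,
                                 window_length = 0.5, gap = 0.1) {
  win <- times >= onset_time - gap - window_length & times <= onset_time - gap
  if (!any(win)) stop_pmbr("time axis does not cover the baseline window")
  seg <- bavg[win]
  if (anyNA(seg)) NA_real_ else mean(seg)
}

#' Average per-trial values over blocks
#'
#' @param values per-trial numeric vector (NA for unusable trials)
#' @param blocks integer block index per trial
#' @param usable logical per-trial flag (defaults to `!is.na(values)`)
#' @return tibble with `block`, `mean`, `n_used`, `n_excluded`
#' @export
block_average <- function(values, blocks, usable = !is.na(values)) {
  if (length(values) != length(blocks))
    stop_pmbr("values and blocks must be the same length")
  ids <- sort(unique(blocks))
  out <- lapply(ids, function(b) {
    sel <- blocks == b & usable
    if (!any(sel))
      stop_pmbr("block ", b, " has no usable trials")
    tibble::tibble(block = b, mean = mean(values[sel]),
                   n_used = sum(sel), n_excluded = sum(blocks == b) - sum(sel))
  })
  do.call(rbind, out)
}

#' Full spectral analysis of one subject's epoched EEG
#'
#' Band-pass filters the epochs, runs the Morlet decomposition block by
#' block, normalizes power relative to the block average, and extracts the
#' per-trial PMBR and baseline beta power.
#'
#' @param eeg numeric matrix, samples x trials (one epoch per column)
#' @param sfreq sampling rate in Hz
#' @param onsets per-trial movement onset times within the epoch (s); also
#'   used as the movement-offset proxy for the PMBR search window
#' @param blocks integer block index per trial
#' @param freqs analysis frequencies (default 5:35 Hz)
#' @param band beta band (default 13-30 Hz)
#' @param n_cycles Morlet cycles (default 7)
#' @param filter_band preprocessing band-pass (default 5-35 Hz); NULL to skip
#' @param norm_method normalization order, see [block_normalize()]
#' @return list with `trials` (tibble: trial, block, onset_s, peak_time_s,
#'   pmbr_pct, baseline_pct, usable, truncated) and `blocks` (tibble:
#'   block, pmbr_pct, baseline_pct, n_used, n_excluded)
#' @export
analyze_subject_eeg <- function(eeg, sfreq, onsets, blocks,
                                freqs = 5:35, band = c(13, 30),
                                n_cycles = 7, filter_band = c(5, 35),
                                norm_method = "log_then_norm",
                                search_window = 2, avg_window = 0.2) {
  eeg <- as.matrix(eeg)
  n_trials <- ncol(eeg)
  if (length(onsets) != n_trials || length(blocks) != n_trials)
    stop_pmbr("onsets and blocks must have one entry per trial")
  if (!is.null(filter_band))
    eeg <- bandpass(eeg, filter_band[1], filter_band[2], sfreq)
  peak_time <- pmbr <- basel <- rep(NA_real_, n_trials)
  usable <- truncated <- rep(FALSE, n_trials)
  bandcols <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(bandcols)) stop_pmbr("no analysis frequencies inside the band")
  for (b in sort(unique(blocks))) {
    tr <- which(blocks == b)
    tf <- morlet_power(eeg[, tr, drop = FALSE], sfreq, freqs, n_cycles)
    norm <- block_normalize(tf$power, tf$valid, rep(b, length(tr)),
                            method = norm_method)
    # band average for all trials at once: (freq, time, trial) -> (time, trial)
    bavg <- colMeans(aperm(norm[, bandcols, , drop = FALSE], c(2, 1, 3)))
    for (k in seq_along(tr)) {
      i <- tr[k]
      pm <- extract_pmbr_series(bavg[, k], tf$times, onsets[i],
                                search_window, avg_window)
      peak_time[i] <- pm$peak_time; pmbr[i] <- pm$pmbr
      usable[i] <- pm$usable; truncated[i] <- pm$truncated
      basel[i] <- baseline_beta_series(bavg[, k], tf$times, onsets[i])
    }
  }
  trials <- tibble::tibble(trial = seq_len(n_trials), block = blocks,
                           onset_s = onsets, peak_time_s = peak_time,
                           pmbr_pct = pmbr, baseline_pct = basel,
                           usable = usable, truncated = truncated)
  bp <- block_average(trials$pmbr_pct, trials$block, trials$usable)
  bb <- block_average(trials$baseline_pct, trials$block,
                      !is.na(trials$baseline_pct))
  blocks_tbl <- tibble::tibble(block = bp$block, pmbr_pct = bp$mean,
                               baseline_pct = bb$mean, n_used = bp$n_used,
                               n_excluded = bp$n_excluded)
  list(trials = trials, blocks = blocks_tbl)
}
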
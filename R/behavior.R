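#' Per-block mean absolute directional error (learning curve)
#'
#' @param records tibble of trial records with `block` and `error_deg`
#' @return tibble with `block` and `mean_abs_error`
#' @export
learning_curve <- function(records) {
  check_records(records)
  ids <- sort(unique(records$block))
  m <- vapply(ids, function(b) {
    e <- records$error_deg[records$block == b]
    if (!length(e)) stop_pmbr("block ", b, " is empty")
    mean(abs(e))
  }, numeric(1))
  tibble::tibble(block = ids, mean_abs_error = m)
}

check_records <- function(records) {
  if (!all(c("block", "error_deg") %in% names(records)))
    stop_pmbr("records must have `block` and `error_deg` columns")
  if (anyNA(records$error_deg))
    stop_pmbr("records contain missing errors")
  invisible(records)
}

#' Learning rate from a block learning curve
#'
#' `(E_first - E_plateau) / E_first`, where `E_first` is the first-block
#' mean absolute error (trials 1-25) and `E_plateau` the mean over the
#' plateau blocks (blocks 9-12, trials 201-300, by default). Negative
#' values (worsening) pass through unclamped; a rate of 1 is perfect.
#'
#' @param curve tibble from [learning_curve()] (or a plain vector of block
#'   means)
#' @param plateau_blocks block indices of the learning plateau; defaults to
#'   the last third of the blocks (9-12 in the 12-block design)
#' @return dimensionless learning rate, or `NA` if the initial error is 0
#' @export
learning_rate <- function(curve, plateau_blocks = NULL) {
  v <- if (is.data.frame(curve)) curve$mean_abs_error else as.numeric(curve)
  plateau_blocks <- plateau_blocks %||% ((2 * length(v)) %/% 3 + 1):length(v)
  if (v[1] == 0) return(NA_real_)
  (v[1] - mean(v[plateau_blocks])) / v[1]
}

#' Intertrial variability per block
#'
#' Sample SD (n-1 denominator) of the signed directional errors within each
#' block.
#'
#' @inheritParams learning_curve
#' @return tibble with `block` and `sd_error`
#' @export
intertrial_variability <- function(records) {
  check_records(records)
  ids <- sort(unique(records$block))
  s <- vapply(ids, function(b) {
    e <- records$error_deg[records$block == b]
    if (length(e) < 2) stop_pmbr("block ", b, " has fewer than 2 trials")
    stats::sd(e)
  }, numeric(1))
  tibble::tibble(block = ids, sd_error = s)
}

#' Decay of intertrial variability over learning
#'
#' SD over the first block (trials 1-25) minus the SD over the pooled
#' plateau trials (201-300 by default).
#'
#' @inheritParams learning_curve
#' @param plateau_trials trial indices of the learning plateau; defaults to
#'   the last third of the trials (201-300 in the 300-trial design)
#' @return decay in degrees
#' @export
variability_decay <- function(records, plateau_trials = NULL) {
  check_records(records)
  n <- max(records$trial)
  plateau_trials <- plateau_trials %||% ((2 * n) %/% 3 + 1):n
  first <- records$error_deg[records$block == min(records$block)]
  plateau <- records$error_deg[records$trial %in% plateau_trials]
  if (length(first) < 2 || length(plateau) < 2)
    stop_pmbr("need >= 2 trials in the first block and in the plateau")
  stats::sd(first) - stats::sd(plateau)
}

#' Mean absolute trial-to-trial error change per block
#'
#' Mean of |e_t - e_(t-1)| over consecutive within-block pairs only (pairs
#' spanning a block boundary are excluded).
#'
#' @inheritParams learning_curve
#' @return tibble with `block` and `mean_abs_change`
#' @export
trial_to_trial_change <- function(records) {
  check_records(records)
  ids <- sort(unique(records$block))
  m <- vapply(ids, function(b) {
    e <- records$error_deg[records$block == b]
    if (length(e) < 2) stop_pmbr("block ", b, " has fewer than 2 trials")
    mean(abs(diff(e)))
  }, numeric(1))
  tibble::tibble(block = ids, mean_abs_change = m)
}

#' Lag-1 autocorrelation over session halves
#'
#' Pearson correlation between consecutive signed errors (e_t, e_(t+1)),
#' computed separately over the first and second halves of the session
#' (trials 1-150 and 151-300 by default); short-series ACF estimates are
#' biased, which is why halves rather than blocks are used. The decay is
#' first-half minus second-half ACF(1).
#'
#' @inheritParams learning_curve
#' @param half_size trials per half (default half the session)
#' @return tibble with `acf1_first`, `acf1_second`, `acf1_decay`
#' @export
acf1_halves <- function(records, half_size = NULL) {
  check_records(records)
  e <- records$error_deg[order(records$trial)]
  n <- length(e)
  half_size <- half_size %||% (n %/% 2)
  acf1 <- function(x) {
    if (length(x) < 3) stop_pmbr("each half needs >= 3 trials")
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x[-length(x)], x[-1])
  }
  a1 <- acf1(e[seq_len(half_size)])
  a2 <- acf1(e[(half_size + 1):n])
  tibble::tibble(acf1_first = a1, acf1_second = a2, acf1_decay = a1 - a2)
}

#' Manipulative complexity of a joint-velocity matrix
#'
#' Eigen-decomposes the sample covariance of the joint velocities,
#' normalizes the eigenvalues to proportions, and returns the normalized
#' eigenvalue entropy `C = -sum(p_i log p_i) / log(N)` with N the number of
#' joints (0 * log 0 := 0). C = 1 when all principal components contribute
#' equally; C = 0 when a single component explains all variability.
#'
#' @param velocities numeric matrix, samples x joints
#' @return complexity C in \[0, 1\]
#' @export
manipulative_complexity <- function(velocities) {
  velocities <- as.matrix(velocities)
  if (nrow(velocities) <= ncol(velocities))
    stop_pmbr("need more samples than joints")
  ev <- eigen(stats::cov(velocities), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sum(ev) == 0) stop_pmbr("zero total variance")
  p <- ev / sum(ev)
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(ncol(velocities))
}

#' Peak head acceleration per trial and per block
#'
#' Maximum acceleration magnitude within the PMBR interval
#' (`[onset, onset + window]`) of each trial, then block-averaged.
#'
#' @param accel matrix samples x trials of acceleration magnitude
#' @param times sample times within the epoch (s)
#' @param onsets per-trial movement onset/offset time (s)
#' @param blocks integer block index per trial
#' @param window interval length after onset in s (default 2)
#' @return list with `trials` (tibble: trial, block, peak_accel) and
#'   `blocks` (tibble: block, peak_accel)
#' @export
head_movement_summary <- function(accel, times, onsets, blocks, window = 2) {
  accel <- as.matrix(accel)
  if (length(times) != nrow(accel))
    stop_pmbr("times must match the number of samples")
  peak <- vapply(seq_len(ncol(accel)), function(i) {
    win <- times >= onsets[i] & times <= onsets[i] + window
    if (!any(win)) return(NA_real_)
    max(abs(accel[win, i]))
  }, numeric(1))
  skipped <- is.na(peak)
  ba <- block_average(peak, blocks, !skipped)
  list(trials = tibble::tibble(trial = seq_len(ncol(accel)), block = blocks,
                               peak_accel = peak),
       blocks = tibble::tibble(block = ba$block, peak_accel = ba$mean))
}

#' Behavioral skill-learning summary for one subject
#'
#' @param records trial records (from [track_trials()] or equivalent)
#' @param kinematics optional list of per-block joint-velocity matrices
#' @return list with `blocks` (tibble: block, mean_abs_error, sd_error,
#'   mean_abs_change, complexity) and `subject` (tibble: learning_rate,
#'   acf1_first, acf1_second, acf1_decay, variability_decay)
#' @export
behavior_summary <- function(records, kinematics = NULL) {
  lc <- learning_curve(records)
  iv <- intertrial_variability(records)
  tc <- trial_to_trial_change(records)
  blocks <- tibble::tibble(block = lc$block,
                           mean_abs_error = lc$mean_abs_error,
                           sd_error = iv$sd_error,
                           mean_abs_change = tc$mean_abs_change)
  blocks$complexity <- if (is.null(kinematics)) NA_real_ else
    vapply(kinematics, manipulative_complexity, numeric(1))
  acf <- acf1_halves(records)
  subject <- tibble::tibble(
    learning_rate = learning_rate(lc),
    acf1_first = acf$acf1_first, acf1_second = acf$acf1_second,
    acf1_decay = acf$acf1_decay,
    variability_decay = variability_decay(records))
  list(blocks = blocks, subject = subject)
}
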
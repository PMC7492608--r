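#' Detect cue-ball movement onset from a ball track
#'
#' The onset is the time of the first sample at which the cue-ball centre
#' lies outside the axis-aligned bounding box (half-width
#' `geometry$box_half_width`, 20 mm by default) centred on its initial
#' position.
#'
#' @param track data frame with `time_s`, `cue_x_mm`, `cue_y_mm` (and
#'   target columns), as produced by [generate_ball_track()] or read from a
#'   tracking CSV
#' @param geometry a [table_geometry()]
#' @return onset time in seconds, or `NA` if the ball never leaves the box
#'   ("no shot detected")
#' @export
detect_onset <- function(track, geometry = table_geometry()) {
  check_track(track)
  detect_onset_xy(track$time_s, cbind(track$cue_x_mm, track$cue_y_mm),
                  geometry$box_half_width)
}

detect_onset_xy <- function(time, cue, half_width) {
  out <- which(pmax(abs(cue[, 1] - cue[1, 1]),
                    abs(cue[, 2] - cue[1, 2])) > half_width)
  if (!length(out)) return(NA_real_)
  time[out[1]]
}

check_track <- function(track) {
  need <- c("time_s", "cue_x_mm", "cue_y_mm", "target_x_mm", "target_y_mm")
  miss <- setdiff(need, names(track))
  if (length(miss)) stop_pmbr("track is missing columns: ",
                              paste(miss, collapse = ", "))
  if (any(diff(track$time_s) <= 0))
    stop_pmbr("track timestamps must be strictly increasing")
  if (!all(is.finite(as.matrix(track[need]))))
    stop_pmbr("non-finite coordinates in track")
  invisible(track)
}

#' Sample index of peak ball speed
#'
#' Speed is computed by central finite differences after a 5-sample moving
#' average smooth of each coordinate (25 ms at 200 Hz); returns the index
#' of the maximum speed, ties broken to the earliest sample.
#'
#' @param positions two-column matrix (x, y) of positions
#' @param dt sample interval in s (only scales speeds; does not affect the
#'   argmax)
#' @param floor minimum peak speed (units of `positions` per s) below which
#'   "no movement" is reported
#' @return sample index of peak speed, or `NA` if the ball never moves
#' @export
peak_speed_sample <- function(positions, dt = 1, floor = 1e-6) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 3) stop_pmbr("need at least 3 samples")
  sm <- apply(positions, 2, function(v)
    stats::filter(v, rep(1 / 5, 5), sides = 2))
  # moving average is NA at the 2 edge samples; fall back to raw there
  sm[is.na(sm)] <- positions[is.na(sm)]
  vx <- (sm[c(2:n, n), 1] - sm[c(1, 1:(n - 1)), 1])
  vy <- (sm[c(2:n, n), 2] - sm[c(1, 1:(n - 1)), 2])
  span <- c(1, rep(2, n - 2), 1) * dt
  speed <- sqrt(vx^2 + vy^2) / span
  if (max(speed) < floor) return(NA_integer_)
  which.max(speed)
}

signed_angle <- function(ref, v) {
  atan2(ref[1] * v[2] - ref[2] * v[1], ref[1] * v[1] + ref[2] * v[2]) * 180 / pi
}

#' Signed directional error of a shot
#'
#' The target-ball movement angle is the angle of the vector from its
#' initial position to its position at peak speed, measured relative to the
#' straight line from the cue ball's start to the target ball's start. The
#' directional error is that angle minus the pocket angle (the angle of the
#' target-start-to-pocket-centre vector, measured the same way), wrapped to
#' (-180, 180], counterclockwise positive.
#'
#' @inheritParams detect_onset
#' @param speed_floor minimum target-ball peak speed (mm/s) to count as a
#'   shot (default 50)
#' @return signed error in degrees, or `NA` if the target ball never moves
#'   ("no shot")
#' @export
directional_error <- function(track, geometry = table_geometry(),
                              speed_floor = 50) {
  check_track(track)
  directional_error_xy(track$time_s,
                       cbind(track$cue_x_mm, track$cue_y_mm),
                       cbind(track$target_x_mm, track$target_y_mm),
                       geometry, speed_floor)
}

directional_error_xy <- function(time, cue, target, geometry, speed_floor) {
  dt <- stats::median(diff(time))
  ipk <- peak_speed_sample(target, dt = dt, floor = speed_floor)
  if (is.na(ipk)) return(NA_real_)
  start <- target[1, ]
  baseline <- start - cue[1, ]
  move <- target[ipk, ] - start
  ang_move <- signed_angle(baseline, move)
  ang_pocket <- signed_angle(baseline, geometry$pocket - geometry$target_start)
  wrap_angle(ang_move - ang_pocket)
}

#' Assign trials to sets and blocks
#'
#' Contiguous 1-based segmentation: block = ceiling(trial / block_size),
#' set = ceiling(trial / set_size). The default design (300 trials, sets of
#' 50, blocks of 25) yields 6 sets and 12 blocks.
#'
#' @param n_trials number of trials
#' @param set_size trials per set (must be divisible by `block_size`)
#' @param block_size trials per block (must divide `n_trials`)
#' @return tibble with `trial`, `set`, `block`
#' @export
segment_blocks <- function(n_trials, set_size = 50, block_size = 25) {
  n_trials <- assert_count(n_trials, "n_trials")
  set_size <- assert_count(set_size, "set_size")
  block_size <- assert_count(block_size, "block_size")
  if (n_trials %% block_size != 0)
    stop_pmbr("n_trials (", n_trials, ") is not divisible by block_size (",
              block_size, ")")
  if (set_size %% block_size != 0)
    stop_pmbr("set_size (", set_size, ") is not divisible by block_size (",
              block_size, ")")
  trial <- seq_len(n_trials)
  tibble::tibble(trial = trial,
                 set = ceiling(trial / set_size),
                 block = ceiling(trial / block_size))
}

#' Per-trial tracking analysis for one subject
#'
#' Runs onset detection and directional-error computation on every trial's
#' ball track and attaches the set/block segmentation.
#'
#' @param tracks list of per-trial track data frames
#' @param geometry a [table_geometry()]
#' @param set_size,block_size segmentation parameters
#' @return tibble of trial records: `trial`, `set`, `block`, `onset_s`,
#'   `error_deg`
#' @export
track_trials <- function(tracks, geometry = table_geometry(),
                         set_size = 50, block_size = 25) {
  seg <- segment_blocks(length(tracks), set_size, block_size)
  onset <- vapply(tracks, detect_onset, numeric(1), geometry = geometry)
  err <- vapply(tracks, directional_error, numeric(1), geometry = geometry)
  tibble::tibble(trial = seg$trial, set = seg$set, block = seg$block,
                 onset_s = onset, error_deg = err)
}
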
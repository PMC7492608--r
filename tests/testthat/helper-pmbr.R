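# shared fixtures; everything is generated in code

# miniature cohort: 2 subjects, 50 trials (2 blocks), cheap enough for
# file-based smoke tests
mini_config <- function(seed = 7, ...) {
  cohort_config(n_subjects = 2, n_negative_coupling = 1, n_trials = 50,
                set_size = 50, block_size = 25, kin_samples_per_block = 200,
                seed = seed, ...)
}

# spectral settings restricted to the beta band: per-frequency normalization
# makes every beta-band quantity identical to the full 5-35 Hz run (asserted
# in test-spectral.R), at roughly half the compute
beta_spectral <- function() run_config(spectral = list(freqs = 13:30))$spectral

# a constant-valued TFR map for extraction tests
flat_map <- function(value, times, freqs = 20) {
  matrix(value, nrow = length(times), ncol = length(freqs))
}

# straight-line shot track built from explicit geometry (independent of the
# generator): target departs from rest at `roll_deg` relative to the
# cue->target baseline, constant speed
manual_track <- function(roll_deg, geometry, v = 800, sfreq = 200,
                         t_move = 0.1, t_end = 0.6) {
  time <- seq(0, t_end, by = 1 / sfreq)
  th <- roll_deg * pi / 180
  base <- geometry$target_start - geometry$cue_start
  phi <- atan2(base[2], base[1])
  s <- pmax(time - t_move, 0) * v
  data.frame(
    time_s = time,
    cue_x_mm = rep(geometry$cue_start[1], length(time)),
    cue_y_mm = rep(geometry$cue_start[2], length(time)),
    target_x_mm = geometry$target_start[1] + s * cos(phi + th),
    target_y_mm = geometry$target_start[2] + s * sin(phi + th))
}
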
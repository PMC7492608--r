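test_that("band-pass filter has the documented response", {
  sfreq <- 256
  t <- (0:(8 * sfreq - 1)) / sfreq
  mid <- seq(2 * sfreq, 6 * sfreq)        # away from edge roll-off

  y20 <- bandpass(sin(2 * pi * 20 * t), sfreq = sfreq)
  expect_lt(abs(max(abs(y20[mid])) - 1), 0.05)   # passband identity

  y2 <- bandpass(sin(2 * pi * 2 * t), sfreq = sfreq)
  att_db <- 20 * log10(max(abs(y2[mid])))
  expect_lt(att_db, -20)                          # stopband attenuation

  ydc <- bandpass(rep(5, length(t)), sfreq = sfreq)
  expect_lt(max(abs(ydc[mid])), 0.01)             # DC removed (> 54 dB down)

  expect_error(bandpass(t, low = 5, high = 200, sfreq = sfreq), "Nyquist")
})

test_that("Morlet power localizes frequencies and scales quadratically", {
  sfreq <- 256
  t <- (0:(6 * sfreq - 1)) / sfreq
  tf <- morlet_power(sin(2 * pi * 20 * t), sfreq)
  mid <- which(tf$valid[, tf$freqs == 5])          # valid at every frequency
  prof <- colMeans(tf$power[mid, , 1])
  expect_equal(tf$freqs[which.max(prof)], 20)

  two <- sin(2 * pi * 10 * t) + sin(2 * pi * 25 * t)
  tf2 <- morlet_power(two, sfreq)
  prof2 <- colMeans(tf2$power[mid, , 1])
  # two distinct ridges: local maxima at 10 and 25 Hz
  loc_max <- which(diff(sign(diff(prof2))) == -2) + 1
  expect_true(all(c(10, 25) %in% tf2$freqs[loc_max]))

  tf4 <- morlet_power(2 * sin(2 * pi * 20 * t), sfreq)
  expect_equal(tf4$power[mid, , 1], 4 * tf$power[mid, , 1],
               tolerance = 1e-10)

  expect_error(morlet_power(rnorm(100), sfreq), "wavelet")
})

test_that("block normalization is the literal log-then-normalize percent change", {
  # hand-computed two-sample case: ln-power {1, 3} -> {-50, +50}
  p <- array(exp(c(1, 3)), c(2, 1, 1))
  v <- matrix(TRUE, 2, 1)
  out <- block_normalize(p, v, 1L)
  expect_equal(as.numeric(out), c(-50, 50))

  # constant power -> 0 everywhere
  pc <- array(7, c(10, 3, 4))
  vc <- matrix(TRUE, 10, 3)
  expect_true(all(abs(block_normalize(pc, vc, rep(1L, 4))) < 1e-9))

  # zero-mean invariant per block and frequency row (to numerical tolerance)
  set.seed(21)
  pr <- array(exp(rnorm(20 * 3 * 6, mean = 3)), c(20, 3, 6))
  vr <- matrix(TRUE, 20, 3); vr[1:2, ] <- FALSE
  blocks <- rep(1:2, each = 3)
  nr <- block_normalize(pr, vr, blocks)
  for (b in 1:2) for (j in 1:3) {
    m <- mean(nr[vr[, j], j, blocks == b])
    expect_lt(abs(m), 1e-6)
  }
  # edge-flagged samples never carry values
  expect_true(all(is.na(nr[1:2, , ])))

  expect_error(block_normalize(array(c(-1, 2), c(2, 1, 1)), v, 1L),
               "non-positive")
})

test_that("PMBR extraction matches the numeric-integration oracle", {
  sfreq <- 256
  times <- (0:(6 * sfreq - 1)) / sfreq
  A <- 30; tc <- 3.5; sd_e <- 0.15
  bump <- function(t) A * exp(-(t - tc)^2 / (2 * sd_e^2))
  vals <- flat_map(0, times) + bump(times)

  pm <- extract_pmbr(vals, times, freqs = 20, offset_time = 3)
  expect_true(pm$usable)
  expect_lt(abs(pm$peak_time - 0.5), 1 / sfreq + 1e-9)
  oracle <- integrate(bump, 3.4, 3.6)$value / 0.2
  expect_lt(abs(pm$pmbr - oracle) / oracle, 0.01)

  # flat map: PMBR = c, earliest-sample tie rule
  flat <- extract_pmbr(flat_map(2.5, times), times, 20, 3)
  expect_equal(flat$pmbr, 2.5)
  expect_equal(flat$peak_time, 0)

  # two bumps: the larger (earlier) one wins
  vals2 <- flat_map(0, times) + bump(times) + 0.5 * A *
    exp(-(times - 4.5)^2 / (2 * sd_e^2))
  pm2 <- extract_pmbr(vals2, times, 20, 3)
  expect_lt(abs(pm2$peak_time - 0.5), 0.01)

  # peak near the search edge: window truncated and flagged
  edge <- flat_map(0, times)
  edge[, 1] <- edge[, 1] + A * exp(-(times - 3.02)^2 / (2 * 0.05^2))
  pme <- extract_pmbr(edge, times, 20, 3)
  expect_true(pme$truncated)

  # invalid samples inside the search window make the trial unusable
  nav <- flat_map(1, times)
  nav[times > 4 & times < 4.1, 1] <- NA
  expect_false(extract_pmbr(nav, times, 20, 3)$usable)
})

test_that("baseline beta window sits before movement onset", {
  sfreq <- 256
  times <- (0:(6 * sfreq - 1)) / sfreq
  expect_equal(baseline_beta(flat_map(3, times), times, 20, onset_time = 3), 3)
  # post-offset bump does not contaminate the pre-onset baseline
  vals <- flat_map(1, times) + 50 * exp(-(times - 3.5)^2 / (2 * 0.15^2))
  expect_lt(abs(baseline_beta(vals, times, 20, 3) - 1), 0.01)
})

test_that("block averaging handles exclusions and empty blocks", {
  expect_equal(block_average(c(1, 2, 3, 6), rep(1L, 4))$mean, 3)
  v <- rep(2, 25); v[10] <- NA
  ba <- block_average(v, rep(1L, 25))
  expect_equal(ba$mean, 2)
  expect_equal(ba$n_used, 24)
  expect_equal(ba$n_excluded, 1)
  # oracle: recompute with the mask directly
  set.seed(22)
  x <- rnorm(50); use <- runif(50) > 0.2
  blocks <- rep(1:2, each = 25)
  ba2 <- block_average(x, blocks, use)
  expect_equal(ba2$mean[2], mean(x[blocks == 2 & use]))
  expect_error(block_average(rep(NA_real_, 25), rep(1L, 25)), "no usable")
})

test_that("beta-band results are identical when analysing beta rows only", {
  # normalization is per frequency row, so restricting the analysis to
  # 13-30 Hz must reproduce the full 5-35 Hz beta-band outputs exactly
  set.seed(23)
  cfg <- mini_config(seed = 23)
  s <- pmbr:::with_private_seed(5, generate_subject(cfg, "decreaser", 1))
  onsets <- rep(3, 50); blocks <- rep(1:2, each = 25)
  full <- analyze_subject_eeg(s$eeg, 256, onsets, blocks, freqs = 5:35)
  beta <- analyze_subject_eeg(s$eeg, 256, onsets, blocks, freqs = 13:30)
  expect_equal(full$trials$pmbr_pct, beta$trials$pmbr_pct, tolerance = 1e-12)
  expect_equal(full$trials$baseline_pct, beta$trials$baseline_pct,
               tolerance = 1e-12)
})

test_that("group dynamics are invariant to global scaling of the recording", {
  cfg <- mini_config(seed = 29)
  s <- pmbr:::with_private_seed(9, generate_subject(cfg, "increaser", 1))
  onsets <- rep(3, 50); blocks <- rep(1:2, each = 25)
  a1 <- analyze_subject_eeg(s$eeg, 256, onsets, blocks, freqs = 13:30)
  a2 <- analyze_subject_eeg(s$eeg * 2, 256, onsets, blocks, freqs = 13:30)
  # log-transform normalization is not numerically scale-free, but the
  # extracted dynamics must keep their ordering
  expect_gt(cor(a1$trials$pmbr_pct, a2$trials$pmbr_pct), 0.95)
  expect_equal(sign(diff(a1$blocks$pmbr_pct)), sign(diff(a2$blocks$pmbr_pct)))
})
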
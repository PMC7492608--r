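test_that("error series follows the programmed bias/SD schedule", {
  # noise-free case: pure exponential decay of the bias
  p <- list(initial_bias = 10, plateau_bias = 0, initial_sd = 0,
            plateau_sd = 0, decay_constant = 30, ar1_rho = 0)
  e <- generate_error_series(p, 300)
  expect_equal(e[1], 10)
  expect_equal(e, 10 * exp(-(0:299) / 30))
  expect_lt(abs(e[300]), 1e-3)

  # marginal SD matches its schedule at selected trials (Monte Carlo)
  p2 <- list(initial_bias = 0, plateau_bias = 0, initial_sd = 8,
             plateau_sd = 2, decay_constant = 40, ar1_rho = 0.3)
  set.seed(42)
  sims <- replicate(1000, generate_error_series(p2, 120))
  sched <- 2 + 6 * exp(-(c(1, 10, 60, 120) - 1) / 40)
  got <- apply(sims[c(1, 10, 60, 120), ], 1, sd)
  expect_equal(got, sched, tolerance = 0.06)

  expect_error(generate_error_series(list(initial_bias = NaN,
                                          plateau_bias = 0, initial_sd = 1,
                                          plateau_sd = 1, decay_constant = 10,
                                          ar1_rho = 0), 10), "finite")
})

test_that("error series has the programmed AR(1) structure", {
  p <- list(initial_bias = 0, plateau_bias = 0, initial_sd = 3,
            plateau_sd = 3, decay_constant = 50, ar1_rho = 0.5)
  set.seed(1)
  e <- generate_error_series(p, 5000)
  expect_lt(abs(cor(e[-1], e[-5000]) - 0.5), 0.03)

  p$ar1_rho <- 0
  set.seed(2)
  e0 <- generate_error_series(p, 5000)
  expect_lt(abs(cor(e0[-1], e0[-5000])), 0.05)
})

test_that("programmed block PMBR has the requested error coupling", {
  be <- c(9, 8, 7.5, 6, 5.2, 4.8, 4.1, 3.9, 3.6, 3.5, 3.4, 3.3)
  set.seed(3)
  pm <- program_block_pmbr(-1, be)
  expect_equal(cor(pm, be), -1, tolerance = 1e-12)
  expect_true(all(pm > 0))

  # Monte-Carlo oracle: mean fitted r over replicates approaches true_corr
  mean_r <- function(rho) {
    mean(replicate(1000, cor(program_block_pmbr(rho, be), be)))
  }
  set.seed(4)
  expect_lt(abs(mean_r(0)), 0.03)
  # calibration target from the positive-coupling group
  expect_lt(abs(mean_r(0.47) - 0.47), 0.03)

  expect_error(program_block_pmbr(1.2, be), "true_corr")
})

test_that("synthetic EEG bursts drive a monotone extracted PMBR", {
  cal <- pmbr_burst_calibration()
  extract_mean <- function(target, n_blocks = 4) {
    vals <- replicate(n_blocks, {
      eeg <- sapply(1:25, function(i) generate_trial_eeg(target,
                                                         calibration = cal))
      res <- analyze_subject_eeg(eeg, 256, rep(3, 25), rep(1L, 25),
                                 freqs = 13:30, filter_band = NULL)
      mean(res$trials$pmbr_pct)
    })
    mean(vals)
  }
  set.seed(5)
  m0a <- extract_mean(0, 4)
  m0b <- extract_mean(0, 4)
  m30 <- extract_mean(30, 4)
  m50 <- extract_mean(50, 4)
  # null bursts: two independent no-burst batches agree (background only)...
  expect_lt(abs(m0a - m0b), 3)
  # ...and monotonicity: larger targets yield larger extracted PMBR
  expect_lt(m0a, m30)
  expect_lt(m30, m50)

  expect_error(generate_trial_eeg(10, trial_duration = 4, offset_time = 3),
               "offset_time")
  expect_error(generate_trial_eeg(10, trial_duration = -1), "positive")
})

test_that("extracted PMBR peak time tracks the burst envelope peak", {
  # pure 20 Hz Gaussian burst; peak located on the raw band-averaged power
  # (no background, so block normalization does not apply)
  sfreq <- 256
  t <- (0:(6 * sfreq - 1)) / sfreq
  tc <- 3.5
  burst <- 50 * exp(-(t - tc)^2 / (2 * 0.15^2)) * cos(2 * pi * 20 * t)
  tf <- morlet_power(burst, sfreq, freqs = 13:30)
  bavg <- rowMeans(tf$power[, , 1])
  pm <- pmbr:::extract_pmbr_series(bavg, tf$times, offset_time = 3)
  expect_lt(abs(pm$peak_time - (tc - 3)), 0.05)
})

test_that("joint-velocity generator hits the complexity target", {
  set.seed(6)
  v1 <- generate_joint_velocities(1, 20, 5000)
  expect_gte(manipulative_complexity(v1), 0.95)
  v0 <- generate_joint_velocities(0, 20, 5000)
  expect_lte(manipulative_complexity(v0), 0.05)
  v5 <- generate_joint_velocities(0.5, 20, 5000)
  expect_lt(abs(manipulative_complexity(v5) - 0.5), 0.02)
  expect_error(generate_joint_velocities(1.2, 10, 100), "target_C")
})

test_that("ball-track generator round-trips the programmed error", {
  geo <- table_geometry()
  set.seed(8)
  tr0 <- generate_ball_track(0, 1, geo, noise_sd = 0)
  expect_lt(abs(directional_error(tr0, geo)), 0.2)

  trp <- generate_ball_track(5, 1, geo, noise_sd = 0)
  trm <- generate_ball_track(-5, 1, geo, noise_sd = 0)
  ep <- directional_error(trp, geo)
  em <- directional_error(trm, geo)
  expect_equal(ep, -em, tolerance = 1e-6)   # mirror symmetry

  for (e in c(-12.5, -3, 0.7, 9)) {
    tr <- generate_ball_track(e, 1, geo)    # default 0.3 mm noise
    expect_lt(abs(directional_error(tr, geo) - e), 0.2)
  }
})

test_that("cohort generation is deterministic and respects group sizes", {
  cfg <- mini_config(seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$subjects[[1]]$errors, c2$subjects[[1]]$errors)
  expect_identical(c1$subjects[[2]]$eeg, c2$subjects[[2]]$eeg)
  expect_identical(c1$truth$true_corr, c2$truth$true_corr)

  # default group sizes: 16 negative-coupling of 30 (cheap trial count)
  cfg30 <- cohort_config(n_trials = 50, set_size = 50, block_size = 25,
                         kin_samples_per_block = 100, seed = 1)
  co <- generate_cohort(cfg30)
  expect_equal(sum(co$truth$group == "increaser"), 16)
  expect_equal(sum(co$truth$group == "decreaser"), 14)
  expect_true(all(co$truth$true_corr[co$truth$group == "increaser"] < 0))
  expect_true(all(co$truth$true_corr[co$truth$group == "decreaser"] > 0))
})

test_that("pipeline recovers programmed structure from a clean cohort", {
  # noise-free round trip: strong coupling, clean EEG, small error noise
  # (scaled to 6 subjects; the full-cohort version is the acceptance run)
  grp <- list(
    increaser = list(coupling = list(corr_mean = -0.95, corr_sd = 0.02)),
    decreaser = list(coupling = list(corr_mean = 0.95, corr_sd = 0.02)))
  # higher programmed base: the cleaner background shrinks the block-mean
  # log power, which shifts the responsive range of the percent scale up
  cfg <- cohort_config(n_subjects = 6, n_negative_coupling = 3,
                       eeg_snr = 5, pmbr_base = 60, pmbr_scale = 10,
                       groups = grp, kin_samples_per_block = 100, seed = 31)
  ana <- simulate_and_analyze(cfg, spectral = beta_spectral())
  expect_equal(ana$subjects$label, ana$subjects$group_true)

  # extracted block PMBR tracks the programmed values subject by subject
  pc <- sapply(seq_len(6), function(i) cor(ana$pmbr_true[i, ], ana$pmbr[i, ]))
  expect_true(all(pc > 0.9))
})
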
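records_from <- function(errors) {
  n <- length(errors)
  seg <- segment_blocks(n, min(n, 50), min(n, 25))
  tibble::tibble(trial = seg$trial, block = seg$block, error_deg = errors)
}

test_that("learning curve and learning rate follow their definitions", {
  rec <- records_from(rep(10, 300))
  expect_true(all(learning_curve(rec)$mean_abs_error == 10))

  rec2 <- records_from(rep(c(-4, 4), 25))  # 50 trials, 2 blocks
  expect_equal(learning_curve(rec2)$mean_abs_error, c(4, 4))

  expect_equal(learning_rate(c(10, rep(NA, 7), 4, 4, 4, 4),
                             plateau_blocks = 9:12), 0.6)
  expect_equal(learning_rate(rep(5, 12)), 0)
  expect_equal(learning_rate(c(4, rep(6, 11))), -0.5)  # worsening, unclamped
  expect_true(is.na(learning_rate(c(0, rep(1, 11)))))

  # decay-constant recovery on a synthetic exponential cohort
  p <- list(initial_bias = 10, plateau_bias = 1, initial_sd = 0.3,
            plateau_sd = 0.3, decay_constant = 50, ar1_rho = 0)
  set.seed(31)
  rec3 <- records_from(generate_error_series(p, 300))
  lc <- learning_curve(rec3)
  fit <- nls(mean_abs_error ~ a + b * exp(-(block - 1) * 25 / tau), data = lc,
             start = list(a = 1, b = 9, tau = 60))
  expect_lt(abs(coef(fit)[["tau"]] - 50) / 50, 0.2)
})

test_that("intertrial variability and its decay use the sample SD", {
  rec <- records_from(rep(c(-1, 1), 25))
  expect_equal(intertrial_variability(rec)$sd_error[1],
               sd(rep(c(-1, 1), 13)[1:25]))
  expect_equal(intertrial_variability(records_from(rep(2, 50)))$sd_error,
               c(0, 0))
  expect_equal(variability_decay(records_from(rep(2, 300))), 0)

  # hand case: block of {-1, 1} repeated has SD sqrt(n/(n-1) * 1) ~ 1
  e <- rep(c(-1, 1), length.out = 25)
  expect_equal(sd(e), sqrt(sum((e - mean(e))^2) / 24))
})

test_that("trial-to-trial change averages within-block consecutive steps", {
  expect_equal(trial_to_trial_change(records_from(rep(1, 50)))$mean_abs_change,
               c(0, 0))
  rec <- records_from(c(0, 2, -2, rep(0, 22), rep(0, 25)))
  expect_equal(trial_to_trial_change(rec)$mean_abs_change[1],
               mean(abs(diff(c(0, 2, -2, rep(0, 22))))))

  # iid N(0, sigma^2) errors: E|diff| = 2 sigma / sqrt(pi)
  set.seed(32)
  sims <- replicate(400, {
    r <- records_from(rnorm(25, sd = 2))
    r$block <- 1L
    trial_to_trial_change(r)$mean_abs_change
  })
  expect_lt(abs(mean(sims) - 2 * 2 / sqrt(pi)) / (2 * 2 / sqrt(pi)), 0.03)

  # block boundaries are not spanned: a jump between blocks is invisible
  e2 <- c(rep(0, 25), rep(100, 25))
  expect_equal(trial_to_trial_change(records_from(e2))$mean_abs_change,
               c(0, 0))
})

test_that("ACF(1) over halves matches known oracles", {
  alt <- records_from(rep(c(1, -1), 150))
  a <- acf1_halves(alt)
  expect_equal(a$acf1_first, -1, tolerance = 1e-12)
  expect_equal(a$acf1_second, -1, tolerance = 1e-12)
  expect_equal(a$acf1_decay, 0, tolerance = 1e-12)

  # white-noise null: |ACF(1)| < 2/sqrt(150) in at least 90% of simulations
  set.seed(33)
  nulls <- replicate(1000, {
    x <- rnorm(150)
    cor(x[-150], x[-1])
  })
  expect_gte(mean(abs(nulls) < 2 / sqrt(150)), 0.9)

  # AR(1) rho = 0.5: recovery within the known small-sample bias envelope,
  # E[ACF(1)] ~ rho - (1 + 3 rho)/n
  set.seed(34)
  ar <- replicate(1000, {
    x <- as.numeric(arima.sim(list(ar = 0.5), 150))
    cor(x[-150], x[-1])
  })
  expect_lt(abs(mean(ar) - (0.5 - (1 + 3 * 0.5) / 150)), 0.03)

  # time reversal leaves pairwise Pearson ACF(1) unchanged
  set.seed(35)
  e <- rnorm(300)
  expect_equal(acf1_halves(records_from(e))$acf1_first,
               acf1_halves(records_from(rev(e)))$acf1_second,
               tolerance = 1e-12)
})

test_that("manipulative complexity is the normalized eigenvalue entropy", {
  # exact rank-1 data
  z <- rnorm(100)
  v1 <- cbind(z, 2 * z, -z, 0.5 * z)
  expect_equal(manipulative_complexity(v1), 0)

  # exactly two equal eigenvalues among four joints: C = ln2/ln4 = 0.5
  set.seed(36)
  a <- rnorm(200)
  b <- residuals(lm(rnorm(200) ~ a))
  a <- as.numeric(scale(a)); b <- as.numeric(scale(b))
  b <- as.numeric(scale(residuals(lm(b ~ a))))    # exactly orthogonal
  V <- cbind(a, b, 0 * a, 0 * a)
  expect_equal(manipulative_complexity(V), log(2) / log(4), tolerance = 1e-9)

  # invariance to joint reordering and global scaling
  set.seed(37)
  V2 <- generate_joint_velocities(0.6, 8, 500)
  c0 <- manipulative_complexity(V2)
  expect_equal(manipulative_complexity(V2[, sample(8)]), c0,
               tolerance = 1e-9)
  expect_equal(manipulative_complexity(V2 * 3.7), c0, tolerance = 1e-9)

  expect_error(manipulative_complexity(matrix(0, 100, 4)), "variance")
  expect_error(manipulative_complexity(matrix(1:6, 2, 3)), "samples")
})

test_that("head-movement summary masks to the post-offset window", {
  times <- (0:999) / 200
  acc <- matrix(0, 1000, 2)
  blocks <- c(1L, 1L)
  z <- head_movement_summary(acc, times, c(3, 3), blocks)
  expect_equal(z$trials$peak_accel, c(0, 0))

  acc[700, 1] <- 5        # t = 3.5 s, inside [3, 5]
  acc[200, 2] <- 9        # t = 1.0 s, outside the window
  z2 <- head_movement_summary(acc, times, c(3, 3), blocks)
  expect_equal(z2$trials$peak_accel, c(5, 0))
  expect_equal(z2$blocks$peak_accel, 2.5)
})
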
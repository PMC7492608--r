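test_that("onset detection matches the frame-scan oracle", {
  geo <- table_geometry(cue_start = c(100, 50), target_start = c(400, 50))
  sfreq <- 200
  time <- (0:120) / sfreq
  t_move <- 0.1
  x <- geo$cue_start[1] + pmax(time - t_move, 0) * 400   # +x at 400 mm/s
  track <- data.frame(time_s = time, cue_x_mm = x,
                      cue_y_mm = geo$cue_start[2],
                      target_x_mm = geo$target_start[1],
                      target_y_mm = geo$target_start[2])
  # oracle: first frame with displacement > 20 mm; 400 mm/s and 200 Hz give
  # 2 mm per frame, so the 11th frame after movement start (0.055 s)
  expect_equal(detect_onset(track, geo), t_move + 0.055)

  # 1 mm jitter is far below the 20 mm box: onset unchanged
  set.seed(11)
  jit <- track
  jit$cue_x_mm <- jit$cue_x_mm + rnorm(nrow(jit), sd = 1)
  jit$cue_y_mm <- jit$cue_y_mm + rnorm(nrow(jit), sd = 1)
  expect_equal(detect_onset(jit, geo), t_move + 0.055)

  # stationary cue ball: no shot detected
  still <- track
  still$cue_x_mm <- geo$cue_start[1]
  expect_true(is.na(detect_onset(still, geo)))
})

test_that("directional error matches the trigonometric oracle", {
  geo <- table_geometry(cue_start = c(0, 0), target_start = c(100, 0))
  d <- sqrt(sum((geo$pocket - geo$target_start)^2))
  # place the pocket exactly 30 degrees CCW of the cue->target baseline
  geo$pocket <- geo$target_start + d * c(cos(pi / 6), sin(pi / 6))

  # straight roll into the pocket centre
  expect_equal(directional_error(manual_track(30, geo), geo), 0,
               tolerance = 1e-6)
  # roll at 25 degrees: error = 25 - 30 = -5
  expect_equal(directional_error(manual_track(25, geo), geo), -5,
               tolerance = 1e-6)
  # mirrored trajectory: sign flip, equal magnitude
  expect_equal(directional_error(manual_track(35, geo), geo), 5,
               tolerance = 1e-6)
  # target never moves: no shot
  still <- manual_track(25, geo, v = 0)
  expect_true(is.na(directional_error(still, geo)))
})

test_that("onset and error are invariant to table translation and rotation", {
  geo <- table_geometry()
  set.seed(12)
  track <- generate_ball_track(4, 0.5, geo, noise_sd = 0)
  e0 <- directional_error(track, geo)
  o0 <- detect_onset(track, geo)

  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(250, -120)
  rot <- function(xy) sweep(as.matrix(xy) %*% t(R), 2, shift, `+`)
  cue <- rot(track[, c("cue_x_mm", "cue_y_mm")])
  tgt <- rot(track[, c("target_x_mm", "target_y_mm")])
  track2 <- data.frame(time_s = track$time_s, cue_x_mm = cue[, 1],
                       cue_y_mm = cue[, 2], target_x_mm = tgt[, 1],
                       target_y_mm = tgt[, 2])
  geo2 <- geo
  geo2$cue_start <- as.numeric(rot(rbind(geo$cue_start)))
  geo2$target_start <- as.numeric(rot(rbind(geo$target_start)))
  geo2$pocket <- as.numeric(rot(rbind(geo$pocket)))

  expect_equal(directional_error(track2, geo2), e0, tolerance = 1e-9)
  expect_equal(detect_onset(track2, geo2), o0)
})

test_that("peak-speed sample matches a brute-force oracle", {
  # trapezoidal speed profile: ramp up, plateau, ramp down
  v <- c(seq(0, 400, length.out = 20), rep(400, 10),
         seq(400, 0, length.out = 20))
  pos <- cbind(cumsum(v) / 200, 0)
  ipk <- peak_speed_sample(pos, dt = 1 / 200)
  # oracle: recompute smoothed central-difference speeds directly
  sm <- stats::filter(pos[, 1], rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- pos[is.na(sm), 1]
  n <- length(sm)
  sp <- abs(sm[c(2:n, n)] - sm[c(1, 1:(n - 1))]) /
    (c(1, rep(2, n - 2), 1) / 200)
  expect_equal(ipk, which.max(sp))
  expect_true(ipk >= 20 && ipk <= 30)      # inside the plateau

  # constant velocity: every sample attains (numerically) maximal speed;
  # the returned index must be one of them (ties break toward the earliest
  # exact maximum; smoothing arithmetic makes exact ties data-dependent)
  pos2 <- cbind(as.numeric(0:49), 0)
  i2 <- peak_speed_sample(pos2)
  sm2 <- stats::filter(pos2[, 1], rep(1 / 5, 5), sides = 2)
  sm2[is.na(sm2)] <- pos2[is.na(sm2), 1]
  sp2 <- abs(sm2[c(2:50, 50)] - sm2[c(1, 1:49)]) / c(1, rep(2, 48), 1)
  expect_gte(sp2[i2], max(sp2) * (1 - 1e-12))

  # no movement
  expect_true(is.na(peak_speed_sample(cbind(rep(1, 10), rep(2, 10)))))
  expect_error(peak_speed_sample(cbind(1:2, 1:2)), "3 samples")
})

test_that("trials segment into the experimental block structure", {
  seg <- segment_blocks(300, 50, 25)
  expect_equal(max(seg$block), 12)
  expect_equal(max(seg$set), 6)
  expect_equal(as.numeric(table(seg$block)), rep(25, 12))
  expect_equal(as.numeric(table(seg$set)), rep(50, 6))
  # closed-form index arithmetic
  expect_equal(seg$set[seg$trial == 51], 2)
  expect_equal(seg$block[seg$trial == 51], 3)

  one <- segment_blocks(25, 25, 25)
  expect_equal(unique(one$block), 1)

  expect_error(segment_blocks(301, 50, 25), "divisible")
  expect_error(segment_blocks(300, 60, 25), "divisible")
})
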
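#' Simulate a joint-velocity matrix with a target manipulative complexity
#'
#' Draws latent standard-normal components, assigns them a geometric
#' eigenvalue profile (variance of component i proportional to r^(i-1)),
#' and solves for the decay ratio r by bisection so that the manipulative
#' complexity of the *sample* covariance of the returned matrix is within
#' tolerance of `target_C`. The scaled latent matrix is then mixed through a
#' random orthogonal rotation, which leaves the covariance eigenvalues (and
#' hence the complexity) unchanged.
#'
#' @param target_C target complexity in \[0, 1\] (1 = all components equal,
#'   0 = one component dominates)
#' @param n_joints number of joints (columns), >= 2
#' @param n_samples number of velocity samples (rows), > n_joints
#' @param tol bisection tolerance on the achieved complexity (default 0.005)
#' @return numeric matrix, `n_samples` x `n_joints`
#' @export
generate_joint_velocities <- function(target_C, n_joints, n_samples,
                                      tol = 0.005) {
  assert_finite_scalar(target_C, "target_C")
  if (target_C < 0 || target_C > 1)
    stop_pmbr("target_C must lie in [0, 1]")
  n_joints <- assert_count(n_joints, "n_joints", min = 2L)
  n_samples <- assert_count(n_samples, "n_samples", min = n_joints + 1L)

  L <- matrix(stats::rnorm(n_samples * n_joints), n_samples, n_joints)
  G <- crossprod(scale(L, center = TRUE, scale = FALSE)) / (n_samples - 1)

  c_of_r <- function(log_r) {
    lam <- exp(log_r * (seq_len(n_joints) - 1))
    s <- sqrt(lam)
    ev <- eigen(G * tcrossprod(s), symmetric = TRUE, only.values = TRUE)$values
    p <- pmax(ev, 0); p <- p / sum(p)
    nz <- p > 0
    -sum(p[nz] * log(p[nz])) / log(n_joints)
  }

  lo <- -14; hi <- 0           # log decay ratio
  c_lo <- c_of_r(lo); c_hi <- c_of_r(hi)
  if (target_C >= c_hi) log_r <- hi
  else if (target_C <= c_lo) log_r <- lo
  else {
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      cm <- c_of_r(mid)
      if (abs(cm - target_C) < tol / 2) break
      if (cm < target_C) lo <- mid else hi <- mid
    }
    log_r <- (lo + hi) / 2
  }
  lam <- exp(log_r * (seq_len(n_joints) - 1))
  X <- sweep(L, 2, sqrt(lam), `*`)
  Q <- qr.Q(qr(matrix(stats::rnorm(n_joints^2), n_joints)))
  X %*% Q
}

#' Simulate per-trial head-acceleration traces
#'
#' Background accelerometer noise plus a movement-related bump (Gaussian
#' envelope) whose magnitude varies across trials independently of the
#' programmed PMBR, for the head-movement control analysis.
#'
#' @param n_trials number of trials
#' @param trial_duration epoch length in s
#' @param offset_time movement offset within the epoch, s
#' @param sfreq sampling rate in Hz
#' @return matrix, samples x trials, acceleration magnitude (m/s^2-like units)
#' @export
generate_head_accel <- function(n_trials, trial_duration = 6,
                                offset_time = 3, sfreq = 200) {
  n <- round(trial_duration * sfreq)
  t <- (seq_len(n) - 1) / sfreq
  env <- exp(-(t - (offset_time + 0.4))^2 / (2 * 0.3^2))
  sapply(seq_len(n_trials), function(i) {
    mag <- stats::rlnorm(1, meanlog = 0, sdlog = 0.4)
    abs(0.1 * stats::rnorm(n) + mag * env)
  })
}
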
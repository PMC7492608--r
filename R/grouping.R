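#' Subject-level PMBR-error correlation
#'
#' Pearson product-moment correlation between the block-averaged PMBR
#' values and the block mean absolute directional errors.
#'
#' @param block_pmbr,block_error aligned numeric vectors (one value per
#'   block)
#' @return Pearson r, or `NA` if either series has zero variance
#' @export
pmbr_error_correlation <- function(block_pmbr, block_error) {
  if (length(block_pmbr) != length(block_error))
    stop_pmbr("series must be the same length")
  if (anyNA(block_pmbr) || anyNA(block_error))
    stop_pmbr("missing block values")
  if (stats::sd(block_pmbr) == 0 || stats::sd(block_error) == 0)
    return(NA_real_)
  stats::cor(block_pmbr, block_error)
}

# ---- Gaussian mixture model (diagonal covariance) ------------------------

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(x, 1, function(row)
      min(colSums((t(centers[seq_len(j - 1), , drop = FALSE]) - row)^2)))
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
  }
  centers
}

# one EM run; returns NULL on degeneracy (vanishing component weight or
# variance collapse onto a few points, the unbounded-likelihood spike)
gmm_em <- function(x, k, tol = 1e-6, max_iter = 500) {
  n <- nrow(x); d <- ncol(x)
  mu <- kmeanspp_init(x, k)
  sigma2 <- matrix(rep(apply(x, 2, stats::var) + 1e-12, each = k), k, d)
  w <- rep(1 / k, k)
  floor_var <- 1e-8 * max(apply(x, 2, stats::var), 1e-12)
  # reject likelihood-spike solutions (component SD below 5% of the data
  # SD): in unequal-variance mixtures the likelihood is unbounded at such
  # spikes, so the meaningful estimate is the best interior optimum
  collapse_var <- 2.5e-3 * max(apply(x, 2, stats::var), 1e-12)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logdens <- vapply(seq_len(k), function(j) {
      rowSums(stats::dnorm(x, rep(mu[j, ], each = n),
                           rep(sqrt(sigma2[j, ]), each = n), log = TRUE))
    }, numeric(n)) + rep(log(w), each = n)
    m <- apply(logdens, 1, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    ll <- sum(lse)
    r <- exp(logdens - lse)
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)           # vanishing component
    w <- nk / n
    mu <- crossprod(r, x) / nk
    for (j in seq_len(k))
      sigma2[j, ] <- pmax(colSums(r[, j] * sweep(x, 2, mu[j, ])^2) / nk[j],
                          floor_var)
    if (any(sigma2 < collapse_var)) return(NULL)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(loglik = ll, weights = w, means = mu, variances = sigma2,
       responsibilities = r)
}

#' Gaussian-mixture model selection by AIC and AICc
#'
#' Fits diagonal-covariance Gaussian mixtures with 1 to `max_components`
#' components by EM (k-means++ initialization, `n_restarts` restarts,
#' log-likelihood tolerance 1e-6), and scores each with
#' AIC = 2k - 2 ln L and its small-sample correction
#' AICc = AIC + 2k(k+1)/(n-k-1), where k = c(2d + 1) - 1 free parameters
#' for c components in d dimensions. An AICc whose correction denominator
#' is non-positive is recorded as +Inf and never selected. The selected
#' count minimizes AICc.
#'
#' Degenerate EM runs are restarted: a component whose weight vanishes, or
#' whose variance collapses onto a few points (component SD below 5% of
#' the data SD — the unbounded-likelihood spike of unequal-variance
#' mixtures), does not count as a fit; a component count whose restarts
#' all degenerate is marked infeasible (+Inf).
#'
#' @param x numeric vector or matrix (n x d)
#' @param max_components largest component count to try (default 5)
#' @param n_restarts EM restarts per count (default 10)
#' @param seed optional private seed for the restarts
#' @return list of class `gmm_selection`: `curve` (tibble: n_components,
#'   loglik, n_params, aic, aicc), `selected` (argmin AICc),
#'   `selected_aic`, and `fits` (per-count EM fits)
#' @export
gmm_select <- function(x, max_components = 5, n_restarts = 10, seed = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop_pmbr("data must be finite")
  n <- nrow(x); d <- ncol(x)
  run <- function() {
    fits <- vector("list", max_components)
    rows <- lapply(seq_len(max_components), function(k) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- gmm_em(x, k)
        if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
          best <- fit
      }
      fits[k] <<- list(best)         # keep NULL slots (all-degenerate count)
      n_par <- k * (2 * d + 1) - 1
      if (is.null(best))
        return(tibble::tibble(n_components = k, loglik = NA_real_,
                              n_params = n_par, aic = Inf, aicc = Inf))
      aic <- 2 * n_par - 2 * best$loglik
      aicc <- if (n - n_par - 1 > 0)
        aic + 2 * n_par * (n_par + 1) / (n - n_par - 1) else Inf
      tibble::tibble(n_components = k, loglik = best$loglik,
                     n_params = n_par, aic = aic, aicc = aicc)
    })
    list(curve = do.call(rbind, rows), fits = fits)
  }
  res <- if (is.null(seed)) run() else with_private_seed(seed, run())
  curve <- res$curve
  structure(list(curve = curve,
                 selected = curve$n_components[which.min(curve$aicc)],
                 selected_aic = curve$n_components[which.min(curve$aic)],
                 fits = res$fits),
            class = "gmm_selection")
}

# ---- fuzzy c-means -------------------------------------------------------

fcm_run <- function(x, c, m, tol, max_iter) {
  n <- nrow(x)
  centers <- x[sample.int(n, c), , drop = FALSE]
  expo <- 2 / (m - 1)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(c), function(j)
      colSums((t(x) - centers[j, ])^2), numeric(n))
    d2 <- pmax(d2, 1e-12)
    inv <- d2^(-expo / 2)                 # ||x - v||^(-2/(m-1))
    u <- inv / rowSums(inv)
    um <- u^m
    new_centers <- crossprod(um, x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- vapply(seq_len(c), function(j)
    colSums((t(x) - centers[j, ])^2), numeric(n))
  list(membership = u, centers = centers,
       objective = sum(u^m * pmax(d2, 0)))
}

#' Fuzzy c-means clustering
#'
#' Standard FCM alternating optimization: memberships updated with exponent
#' -1/(m-1) on squared distances, centers as membership^m-weighted means,
#' iterated until the center shift falls below `tol` or `max_iter` is
#' reached; the best of `n_restarts` random restarts (by the FCM objective)
#' is returned and each point hard-assigned to its maximum-membership
#' cluster.
#'
#' @param x numeric vector or matrix (n x d)
#' @param c number of clusters (>= 2, < n)
#' @param m fuzzifier (default 2)
#' @param tol convergence tolerance on the center shift (default 1e-6)
#' @param max_iter iteration cap (default 1000)
#' @param n_restarts random restarts (default 10)
#' @param seed optional private seed
#' @return list of class `fcm_fit`: `membership` (n x c, rows sum to 1),
#'   `centers`, `objective`, `cluster` (hard assignment)
#' @export
fcm_cluster <- function(x, c, m = 2, tol = 1e-6, max_iter = 1000,
                        n_restarts = 10, seed = NULL) {
  x <- as.matrix(x)
  c <- assert_count(c, "c", min = 2L)
  if (nrow(x) <= c) stop_pmbr("need more points than clusters")
  if (m <= 1) stop_pmbr("fuzzifier m must be > 1")
  run <- function() {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- fcm_run(x, c, m, tol, max_iter)
      dup <- min(stats::dist(fit$centers)) < 1e-9
      if (dup) next
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    best
  }
  best <- if (is.null(seed)) run() else with_private_seed(seed, run())
  if (is.null(best))
    stop_pmbr("all FCM restarts produced coincident centers")
  structure(list(membership = best$membership, centers = best$centers,
                 objective = best$objective,
                 cluster = max.col(best$membership)),
            class = "fcm_fit")
}

#' Within/between fuzzy cluster validity index
#'
#' Ratio of the membership-weighted within-cluster variation to the minimum
#' squared separation between cluster centers:
#' `sum_k sum_i u_ik^m ||x_i - v_k||^2 / (n * min_(j!=k) ||v_j - v_k||^2)`.
#' Smaller is better; the selected cluster count minimizes the index.
#'
#' @param x data matrix (n x d)
#' @param membership n x c membership matrix
#' @param centers c x d center matrix
#' @param m fuzzifier (default 2)
#' @return validity index (smaller is better); +Inf for coincident centers
#' @export
validity_index <- function(x, membership, centers, m = 2) {
  x <- as.matrix(x); centers <- as.matrix(centers)
  n <- nrow(x); c <- nrow(centers)
  d2 <- vapply(seq_len(c), function(j)
    colSums((t(x) - centers[j, ])^2), numeric(n))
  within <- sum(membership^m * d2)
  sep <- min(stats::dist(centers))^2
  if (sep < 1e-12) return(Inf)
  within / (n * sep)
}

#' FCM cluster-count selection by the validity index
#'
#' Runs [fcm_cluster()] for each candidate count and evaluates
#' [validity_index()]; the selected count minimizes the index.
#'
#' @inheritParams fcm_cluster
#' @param c_range candidate cluster counts (default 2:10)
#' @return list of class `fcm_selection`: `curve` (tibble: n_clusters,
#'   validity), `selected`, `fits`
#' @export
fcm_select <- function(x, c_range = 2:10, m = 2, n_restarts = 10,
                       seed = NULL) {
  x <- as.matrix(x)
  c_range <- c_range[c_range < nrow(x)]
  fits <- lapply(c_range, function(c)
    fcm_cluster(x, c, m = m, n_restarts = n_restarts, seed = seed))
  val <- vapply(seq_along(c_range), function(i)
    validity_index(x, fits[[i]]$membership, fits[[i]]$centers, m),
    numeric(1))
  structure(list(curve = tibble::tibble(n_clusters = c_range,
                                        validity = val),
                 selected = c_range[which.min(val)], fits = fits),
            class = "fcm_selection")
}

#' Assign increaser/decreaser labels from the grouping analysis
#'
#' Labels each subject by the posterior of the selected two-component GMM
#' on the correlation vector, names the component with the lower mean
#' correlation `increaser` (negative PMBR-error coupling), and verifies
#' sign purity: every member of one group should share a correlation sign.
#' On impurity the function falls back to sign-based labels with a warning;
#' if the model selection did not choose two components, labels are
#' withheld.
#'
#' @param correlations per-subject PMBR-error correlations
#' @param gmm a `gmm_selection` fitted on `correlations`
#' @return list: `labels` (character or NULL), `sign_pure` (logical),
#'   `diagnostic` (character)
#' @export
assign_groups <- function(correlations, gmm) {
  if (gmm$selected != 2)
    return(list(labels = NULL, sign_pure = NA,
                diagnostic = sprintf(
                  "model selection chose %d components, not 2; labels withheld",
                  gmm$selected)))
  fit <- gmm$fits[[2]]
  comp <- max.col(fit$responsibilities)
  lower <- which.min(fit$means[, 1])
  labels <- ifelse(comp == lower, "increaser", "decreaser")
  pure <- all(correlations[labels == "increaser"] < 0) &&
    all(correlations[labels == "decreaser"] > 0)
  if (!pure) {
    warning("GMM groups are not sign-pure; falling back to sign-based labels")
    labels <- ifelse(correlations < 0, "increaser", "decreaser")
  }
  list(labels = labels, sign_pure = pure,
       diagnostic = if (pure) "two sign-pure groups" else
         "sign impurity; sign-based fallback used")
}

#' Linear trend of group block means
#'
#' Ordinary least squares of the block means on the block index, with the
#' F test of the linear model against the intercept-only model.
#'
#' @param block_values numeric vector of per-block group means
#' @return tibble with `slope`, `intercept`, `f_statistic`, `p_value`,
#'   `r_squared`, `df1`, `df2`
#' @export
trend_fit <- function(block_values) {
  if (anyNA(block_values) || !all(is.finite(block_values)))
    stop_pmbr("block values must be finite")
  if (length(block_values) < 3)
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          f_statistic = NA_real_, p_value = NA_real_,
                          r_squared = NA_real_, df1 = NA_real_,
                          df2 = NA_real_))
  if (stats::sd(block_values) == 0)    # zero-variance response: F is 0
    return(tibble::tibble(slope = 0, intercept = block_values[1],
                          f_statistic = 0, p_value = NA_real_,
                          r_squared = 0, df1 = 1,
                          df2 = length(block_values) - 2))
  b <- seq_along(block_values)
  fit <- stats::lm(block_values ~ b)
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    # a perfect linear fit is a legitimate degenerate input here
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  fstat <- sm$fstatistic
  if (is.null(fstat)) {         # zero-variance response: F undefined/0
    return(tibble::tibble(slope = stats::coef(fit)[2] %||% 0, intercept = stats::coef(fit)[1],
                          f_statistic = 0, p_value = NA_real_,
                          r_squared = 0, df1 = 1, df2 = length(b) - 2))
  }
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 f_statistic = unname(fstat[1]),
                 p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                            lower.tail = FALSE)),
                 r_squared = sm$r.squared,
                 df1 = unname(fstat[2]), df2 = unname(fstat[3]))
}

#' Within-subject control correlations
#'
#' Pearson correlations, per subject, between the block PMBR series and
#' each companion block series (intertrial variability, trial-to-trial
#' change, peak head acceleration), plus a two-sample Welch t-test
#' comparing the coefficient distributions between groups.
#'
#' @param pmbr_blocks n_subjects x n_blocks matrix of block PMBR values
#' @param other_blocks matching matrix of the companion measure
#' @param labels per-subject group labels
#' @return list: `subjects` (tibble: subject, label, r), `group_test`
#'   (tibble: mean per group, t, p)
#' @export
control_correlations <- function(pmbr_blocks, other_blocks, labels) {
  pmbr_blocks <- as.matrix(pmbr_blocks); other_blocks <- as.matrix(other_blocks)
  if (!all(dim(pmbr_blocks) == dim(other_blocks)))
    stop_pmbr("block matrices must have matching dimensions")
  r <- vapply(seq_len(nrow(pmbr_blocks)), function(i) {
    ok <- is.finite(pmbr_blocks[i, ]) & is.finite(other_blocks[i, ])
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(pmbr_blocks[i, ok], other_blocks[i, ok])
  }, numeric(1))
  subjects <- tibble::tibble(subject = seq_along(r), label = labels, r = r)
  gs <- split(r, labels)
  tt <- if (length(gs) == 2 && all(lengths(gs) >= 2))
    tryCatch(stats::t.test(gs[[1]], gs[[2]]), error = function(e) NULL)
  else NULL
  group_test <- tibble::tibble(
    group = names(gs),
    mean_r = vapply(gs, mean, numeric(1), na.rm = TRUE),
    t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    p = if (is.null(tt)) NA_real_ else tt$p.value)
  list(subjects = subjects, group_test = group_test)
}
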
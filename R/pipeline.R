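#' Pipeline run configuration
#'
#' Collects every analysis constant in one place, with defaults equal to
#' the study design values: 5-35 Hz preprocessing band-pass, Morlet
#' frequencies 5-35 Hz in 1 Hz steps (7 cycles), beta band 13-30 Hz, 2-s
#' post-offset peak search, 200-ms averaging window, 25-trial blocks /
#' 50-trial sets, GMM components 1-5 and FCM clusters 2-10.
#'
#' @param cohort a [cohort_config()] for the simulate stage
#' @param out_dir output directory for staged runs
#' @param stages character subset of `c("simulate", "analyze", "report")`
#' @param spectral named list of spectral parameters (see
#'   [analyze_subject_eeg()])
#' @param grouping named list: `max_components`, `c_range`
#' @return object of class `run_config`
#' @export
run_config <- function(cohort = cohort_config(), out_dir = "pmbr-results",
                       stages = c("simulate", "analyze", "report"),
                       spectral = list(), grouping = list()) {
  sp <- utils::modifyList(list(freqs = 5:35, band = c(13, 30), n_cycles = 7,
                               filter_band = c(5, 35),
                               norm_method = "log_then_norm",
                               search_window = 2, avg_window = 0.2), spectral)
  gr <- utils::modifyList(list(max_components = 5, c_range = 2:10), grouping)
  structure(list(cohort = cohort, out_dir = out_dir, stages = stages,
                 spectral = sp, grouping = gr), class = "run_config")
}

#' Analyze one subject of a cohort
#'
#' Tracking (onset + directional error + segmentation), spectral PMBR
#' extraction, behavioral metrics and head-movement summary for a single
#' `pmbr_subject`. Consumes no random numbers.
#'
#' @param s a `pmbr_subject`
#' @param config the `cohort_config` the subject was generated under
#' @param spectral named list of spectral parameters (see [run_config()])
#' @return list with `records`, `spectral`, `behavior`, `head`, `corr`
#' @export
analyze_subject <- function(s, config, spectral = run_config()$spectral) {
  n_trials <- ncol(s$eeg)
  seg <- segment_blocks(n_trials, config$set_size, config$block_size)
  onset <- vapply(seq_len(n_trials), function(i)
    detect_onset_xy(s$track$time, s$track$cue[, , i],
                    s$geometry$box_half_width), numeric(1))
  err <- vapply(seq_len(n_trials), function(i)
    directional_error_xy(s$track$time, s$track$cue[, , i],
                         s$track$target[, , i], s$geometry, 50), numeric(1))
  records <- tibble::tibble(trial = seg$trial, set = seg$set,
                            block = seg$block, onset_s = onset,
                            error_deg = err)
  if (anyNA(records$onset_s) || anyNA(records$error_deg))
    stop_pmbr("subject ", s$subject, ": no shot detected in trial ",
              paste(which(is.na(records$onset_s) | is.na(records$error_deg)),
                    collapse = ", "))
  spec <- analyze_subject_eeg(
    s$eeg, config$sfreq_eeg, records$onset_s, records$block,
    freqs = spectral$freqs, band = spectral$band,
    n_cycles = spectral$n_cycles, filter_band = spectral$filter_band,
    norm_method = spectral$norm_method,
    search_window = spectral$search_window,
    avg_window = spectral$avg_window)
  beh <- behavior_summary(records, s$kinematics)
  t_acc <- (seq_len(nrow(s$head_accel)) - 1) / config$sfreq_track
  head <- head_movement_summary(s$head_accel, t_acc, records$onset_s,
                                records$block, spectral$search_window)
  r <- pmbr_error_correlation(spec$blocks$pmbr_pct,
                              beh$blocks$mean_abs_error)
  list(subject = s$subject, group_true = s$group, true_corr = s$true_corr,
       records = records, spectral = spec, behavior = beh, head = head,
       corr = r)
}

#' Cohort-level analysis
#'
#' Runs [analyze_subject()] on every subject, then the cohort-level
#' grouping: the subject-by-subject PMBR-error correlations are fitted
#' with Gaussian mixtures of 1-5 components (AIC/AICc model selection, on
#' both the 12-dimensional block-PMBR matrix and the 1-dimensional
#' correlation vector), validated by fuzzy c-means with the within/between
#' validity index over 2-10 clusters, labels assigned from the
#' two-component posterior, per-group linear PMBR trends fitted, and the
#' within-subject control correlations (PMBR vs variability,
#' trial-to-trial change, head acceleration) computed.
#'
#' @param cohort a `pmbr_cohort`
#' @param spectral,grouping parameter lists (see [run_config()])
#' @param verbose print per-subject progress
#' @return object of class `pmbr_analysis`; see Details
#' @details The result carries `subjects` (per-subject tibble), the block
#' matrices (`pmbr`, `baseline`, `error`, `sd_error`, `change`,
#' `complexity`, `head`), `gmm_corr`, `gmm_pmbr`, `fcm`, `groups`,
#' `trends` and `controls`.
#' @export
analyze_cohort <- function(cohort, spectral = run_config()$spectral,
                           grouping = run_config()$grouping,
                           verbose = FALSE) {
  per <- lapply(cohort$subjects, function(s) {
    if (verbose) message("subject ", s$subject)
    analyze_subject(s, cohort$config, spectral)
  })
  finish_cohort_analysis(per, cohort$config, grouping)
}

# assemble cohort-level results from per-subject analyses
finish_cohort_analysis <- function(per, config, grouping) {
  nb <- config$n_blocks
  getmat <- function(f) t(vapply(per, f, numeric(nb)))
  pmbr <- getmat(function(a) a$spectral$blocks$pmbr_pct)
  baseline <- getmat(function(a) a$spectral$blocks$baseline_pct)
  errmat <- getmat(function(a) a$behavior$blocks$mean_abs_error)
  sdmat <- getmat(function(a) a$behavior$blocks$sd_error)
  chmat <- getmat(function(a) a$behavior$blocks$mean_abs_change)
  cxmat <- getmat(function(a) a$behavior$blocks$complexity)
  headmat <- getmat(function(a) a$head$blocks$peak_accel)
  subjects <- do.call(rbind, lapply(per, function(a)
    cbind(tibble::tibble(subject = a$subject, group_true = a$group_true,
                         true_corr = a$true_corr, corr = a$corr),
          a$behavior$subject)))

  if (nrow(subjects) >= 5) {
    gmm_corr <- gmm_select(subjects$corr, grouping$max_components,
                           seed = child_seed(config$seed, 777))
    gmm_pmbr <- gmm_select(pmbr, grouping$max_components,
                           seed = child_seed(config$seed, 778))
    fcm <- fcm_select(subjects$corr, grouping$c_range,
                      seed = child_seed(config$seed, 779))
    groups <- assign_groups(subjects$corr, gmm_corr)
  } else {
    # too few subjects for mixture/cluster selection: sign-based labels only
    gmm_corr <- gmm_pmbr <- fcm <- NULL
    groups <- list(labels = NULL, sign_pure = NA,
                   diagnostic = "fewer than 5 subjects; sign-based labels")
  }
  labels <- groups$labels %||% ifelse(subjects$corr < 0,
                                      "increaser", "decreaser")
  subjects$label <- labels

  trends <- lapply(split(seq_len(nrow(pmbr)), labels), function(idx)
    trend_fit(colMeans(pmbr[idx, , drop = FALSE])))
  controls <- list(
    variability = control_correlations(pmbr, sdmat, labels),
    change = control_correlations(pmbr, chmat, labels),
    head = control_correlations(pmbr, headmat, labels))

  structure(list(subjects = subjects, pmbr = pmbr, baseline = baseline,
                 error = errmat, sd_error = sdmat, change = chmat,
                 complexity = cxmat, head = headmat,
                 gmm_corr = gmm_corr, gmm_pmbr = gmm_pmbr, fcm = fcm,
                 groups = groups, trends = trends, controls = controls,
                 config = config),
            class = "pmbr_analysis")
}

#' Simulate and analyze a cohort without materializing raw data
#'
#' Equivalent to `analyze_cohort(generate_cohort(config))` but generates
#' and analyzes one subject at a time, which keeps memory flat for
#' multi-seed recovery runs. Results are identical because the per-subject
#' analysis consumes no random numbers.
#'
#' @inheritParams generate_cohort
#' @param spectral,grouping parameter lists (see [run_config()])
#' @return a `pmbr_analysis` with the cohort truth attached as `truth`
#' @export
simulate_and_analyze <- function(config = cohort_config(),
                                 spectral = run_config()$spectral,
                                 grouping = run_config()$grouping,
                                 geometry = table_geometry()) {
  calibration <- pmbr_burst_calibration(sfreq = config$sfreq_eeg,
                                        trial_duration = config$trial_duration,
                                        offset_time = config$offset_time,
                                        snr = config$eeg_snr)
  groups_true <- rep(c("increaser", "decreaser"),
                     c(config$n_negative_coupling,
                       config$n_subjects - config$n_negative_coupling))
  res <- with_private_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(i) {
      s <- generate_subject(config, groups_true[i], i, geometry, calibration)
      a <- analyze_subject(s, config, spectral)
      a$block_pmbr_true <- s$block_pmbr_true
      a
    })
  })
  out <- finish_cohort_analysis(res, config, grouping)
  out$pmbr_true <- t(vapply(res, function(a) a$block_pmbr_true,
                            numeric(config$n_blocks)))
  out
}

#' @export
print.pmbr_analysis <- function(x, ...) {
  cat("<pmbr_analysis>\n")
  cat(sprintf("  %d subjects, %d blocks\n", nrow(x$subjects),
              ncol(x$pmbr)))
  if (!is.null(x$gmm_corr))
    cat(sprintf("  GMM (correlations) selected %d component(s); FCM validity selected %d cluster(s)\n",
                x$gmm_corr$selected, x$fcm$selected))
  cat(sprintf("  labels: %d increaser / %d decreaser (%s)\n",
              sum(x$subjects$label == "increaser"),
              sum(x$subjects$label == "decreaser"), x$groups$diagnostic))
  for (g in names(x$trends))
    cat(sprintf("  PMBR trend (%s): slope %.3f %%/block, F = %.1f, p = %.2g\n",
                g, x$trends[[g]]$slope, x$trends[[g]]$f_statistic,
                x$trends[[g]]$p_value))
  invisible(x)
}

# tiny stable polynomial hash for the manifest (fits in double precision)
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the staged pipeline
#'
#' `simulate` writes a synthetic cohort under `out_dir/cohort`; `analyze`
#' reads it back and writes the per-subject and cohort-level tables plus a
#' grouping report under `out_dir/analysis`; `report` renders summary
#' tables and figures under `out_dir/report`. Stages whose outputs already
#' exist are skipped (delete the stage directory to force recomputation),
#' and a manifest records the configuration hash and row counts.
#'
#' @param config a [run_config()]
#' @return `out_dir`, invisibly
#' @export
run_pipeline <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cohort_dir <- file.path(out, "cohort")
  ana_dir <- file.path(out, "analysis")

  if ("simulate" %in% config$stages && !file.exists(file.path(cohort_dir, "truth.csv"))) {
    message("stage simulate -> ", cohort_dir)
    generate_cohort(config$cohort, out_dir = cohort_dir)
  }
  if ("analyze" %in% config$stages && !file.exists(file.path(ana_dir, "subjects.csv"))) {
    message("stage analyze -> ", ana_dir)
    cohort <- read_cohort(cohort_dir)
    ana <- analyze_cohort(cohort, config$spectral, config$grouping)
    dir.create(ana_dir, showWarnings = FALSE)
    utils::write.csv(ana$subjects, file.path(ana_dir, "subjects.csv"),
                     row.names = FALSE)
    for (nm in c("pmbr", "baseline", "error", "sd_error", "change",
                 "complexity", "head")) {
      m <- as.data.frame(ana[[nm]])
      names(m) <- sprintf("block_%02d", seq_len(ncol(m)))
      utils::write.csv(cbind(subject = ana$subjects$subject, m),
                       file.path(ana_dir, paste0("blocks_", nm, ".csv")),
                       row.names = FALSE)
    }
    report <- list(
      gmm_correlation = ana$gmm_corr$curve,
      gmm_correlation_selected = ana$gmm_corr$selected,
      gmm_pmbr = ana$gmm_pmbr$curve,
      gmm_pmbr_selected_aic = ana$gmm_pmbr$selected_aic,
      fcm_validity = ana$fcm$curve,
      fcm_selected = ana$fcm$selected,
      grouping = ana$groups$diagnostic,
      labels = ana$subjects$label,
      trends = lapply(ana$trends, as.list),
      controls = lapply(ana$controls, function(ct) ct$group_test))
    jsonlite::write_json(report, file.path(ana_dir, "grouping.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if ("report" %in% config$stages)
    make_report(out)

  manifest <- list(
    package_version = as.character(utils::packageVersion("pmbr")),
    config_hash = config_hash(yaml::as.yaml(unclass(config$cohort))),
    n_subjects = config$cohort$n_subjects,
    n_blocks = config$cohort$n_blocks,
    stages = config$stages)
  if (file.exists(file.path(ana_dir, "subjects.csv")))
    manifest$subject_rows <- nrow(utils::read.csv(file.path(ana_dir, "subjects.csv")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

#' Render tables and figures from a completed pipeline run
#'
#' Reads the analysis stage outputs and writes: group learning curves,
#' group PMBR-by-block curves, the model-selection curves, the
#' distribution of subject correlations, behavioral group contrasts, and
#' (when the cohort truth table is present) a label-recovery confusion
#' matrix. Regeneration is deterministic.
#'
#' @param out_dir pipeline output directory (with `analysis/` inside)
#' @return report directory, invisibly
#' @export
make_report <- function(out_dir) {
  ana_dir <- file.path(out_dir, "analysis")
  if (!file.exists(file.path(ana_dir, "subjects.csv")))
    stop_pmbr("analysis stage outputs not found under ", ana_dir)
  rep_dir <- file.path(out_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  subjects <- utils::read.csv(file.path(ana_dir, "subjects.csv"))
  grouping <- jsonlite::read_json(file.path(ana_dir, "grouping.json"),
                                  simplifyVector = TRUE)
  blocks <- function(nm) utils::read.csv(file.path(ana_dir,
                                                   paste0("blocks_", nm, ".csv")))
  long <- function(nm) {
    m <- blocks(nm)
    do.call(rbind, lapply(seq_len(nrow(m)), function(i)
      data.frame(subject = m$subject[i], label = subjects$label[i],
                 block = seq_len(ncol(m) - 1),
                 value = as.numeric(m[i, -1]), measure = nm)))
  }
  measures <- c("error", "pmbr", "baseline", "sd_error", "change",
                "complexity")
  dat <- do.call(rbind, lapply(measures, long))
  gmeans <- stats::aggregate(value ~ label + block + measure, dat, mean)
  utils::write.csv(gmeans, file.path(rep_dir, "group_block_means.csv"),
                   row.names = FALSE)

  p <- ggplot2::ggplot(gmeans,
                       ggplot2::aes(x = .data$block, y = .data$value,
                                    colour = .data$label)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "block (25 trials)", y = NULL,
                  title = "Group dynamics over blocks") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(rep_dir, "group_dynamics.png"), p,
                  width = 9, height = 6, dpi = 120)

  ph <- ggplot2::ggplot(subjects,
                        ggplot2::aes(x = .data$corr, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 15, colour = "white") +
    ggplot2::labs(x = "PMBR-error correlation (r)", y = "subjects",
                  title = "Subject-by-subject PMBR-error correlations") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(rep_dir, "correlations.png"), ph,
                  width = 6, height = 4, dpi = 120)

  if (length(grouping$gmm_correlation$n_components) &&
      length(grouping$fcm_validity$n_clusters)) {
    sel <- rbind(
      data.frame(k = grouping$gmm_correlation$n_components,
                 value = grouping$gmm_correlation$aicc,
                 curve = "GMM AICc (correlations)"),
      data.frame(k = grouping$fcm_validity$n_clusters,
                 value = grouping$fcm_validity$validity,
                 curve = "FCM validity"))
    sel <- sel[is.finite(sel$value), ]
    ps <- ggplot2::ggplot(sel, ggplot2::aes(x = .data$k, y = .data$value)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~curve, scales = "free") +
      ggplot2::labs(x = "number of components / clusters", y = "criterion",
                    title = "Model selection") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(rep_dir, "model_selection.png"), ps,
                    width = 8, height = 3.5, dpi = 120)
  }

  utils::write.csv(do.call(rbind, lapply(names(grouping$trends), function(g)
    data.frame(group = g, grouping$trends[[g]]))),
    file.path(rep_dir, "pmbr_trends.csv"), row.names = FALSE)

  truth_path <- file.path(out_dir, "cohort", "truth.csv")
  if (file.exists(truth_path)) {
    truth <- utils::read.csv(truth_path)
    cm <- table(truth = truth$group[match(subjects$subject, truth$subject)],
                label = subjects$label)
    utils::write.csv(as.data.frame(cm),
                     file.path(rep_dir, "label_recovery.csv"),
                     row.names = FALSE)
  }
  invisible(rep_dir)
}
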
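#' Subset epochs or a TFR by trial indices
#'
#' @param epochs An `eeg_epochs`.
#' @param idx Trial indices (rows of the trial table).
#' @return The subset object.
#' @export
subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$trials <- epochs$trials[idx, , drop = FALSE]
  epochs
}

#' @rdname subset_epochs
#' @param tfr An `eeg_tfr` with per-trial power.
#' @export
subset_tfr <- function(tfr, idx) {
  tfr$power <- tfr$power[idx, , , , drop = FALSE]
  tfr$trials <- tfr$trials[idx, , drop = FALSE]
  tfr
}

#' Run the full simulate-to-regression pipeline
#'
#' Executes every stage on one synthetic cohort: trajectory generation,
#' kinematic extraction with 2-SD trial rejection and the extent mixed
#' model; EEG generation, Morlet TFR with whole-epoch baseline, peak
#' frequencies per window with the Friedman/Dunn tests; a
#' repeated-measures cluster permutation test of the target-distance
#' effect on execution-window gamma power; debiased wPLI matrices for
#' the planning, execution and post-movement windows; NBS contrasts
#' (omnibus repeated-measures F and the execution-vs-planning paired t);
#' and the regression screen of per-subject gamma summaries against
#' peak velocity and movement time. Identical configuration and seed
#' give an identical report.
#'
#' @param cfg A `synth_config`; its sizes set the cohort scale.
#' @param n_channels Channels in the generated layout.
#' @param freqs TFR frequency grid (Hz).
#' @param conn_band Band for the connectivity stage, c(lo, hi) Hz.
#' @param decim Temporal decimation of the TFR.
#' @param n_perm Permutations for the cluster and NBS tests.
#' @param nbs_threshold Primary t threshold of the paired NBS contrast;
#'   default the one-sided t quantile at pointwise alpha 0.001.
#' @param out_dir Optional directory; when given, the kinematic table
#'   (CSV), connectivity matrices (TSV) and the report (JSON) are
#'   written there.
#' @param seed Integer seed; every stage derives its own seed from it.
#' @return The run report (nested list), invisibly also written to
#'   `out_dir/report.json` when requested.
#' @export
run_pipeline <- function(cfg = synth_config(),
                         n_channels = 32,
                         freqs = seq(25.5, 80, by = 0.5),
                         conn_band = c(55.5, 80),
                         decim = 2L,
                         n_perm = 200,
                         nbs_threshold = NULL,
                         out_dir = NULL,
                         seed = cfg$seed) {
  seed <- as.integer(seed)
  report <- list(seed = seed,
                 config = list(n_subjects = cfg$n_subjects,
                               n_trials_per_distance =
                                 cfg$n_trials_per_distance,
                               n_channels = n_channels,
                               n_perm = n_perm))
  bands <- gamma_bands(); wins <- analysis_windows()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate -------------------------------------------------------
  layout <- stage("layout", gen_layout(n_channels, seed = seed))
  reaches <- stage("reaches", gen_reach_trials(cfg, seed = seed))

  # --- kinematics -----------------------------------------------------
  kin <- stage("kinematics", kinematics_table(reaches, cfg))
  rej <- stage("rejection", reject_outliers(kin))
  kept <- rej$kept
  lmm <- stage("lmm", compare_lmm(kept$extent_cm, kept$pv_cm_s,
                                  kept$mt_s, kept$subject))
  fx <- lmm$fit_slope$fixed_effects
  report$kinematics <- list(
    n_trials = nrow(kin), n_rejected = length(rej$rejected),
    pv_slope = fx$slope[fx$term == "pv"],
    mt_slope = fx$slope[fx$term == "mt"],
    r2_adjusted = lmm$fit_slope$r2_adjusted,
    bic_intercept = lmm$bic_intercept, bic_slope = lmm$bic_slope,
    lrt_p = lmm$lrt_p, preferred = lmm$preferred)

  # --- EEG + spectral, per subject ------------------------------------
  epochs_all <- stage("eeg", gen_eeg_epochs(reaches, layout, cfg,
                                            seed = seed + 1L))
  plan_ch <- region_channels(layout, cfg$burst_plan$region)
  exec_ch <- region_channels(layout, cfg$burst_exec$region)
  n_subj <- cfg$n_subjects
  distances <- sort(unique(kin$distance_cm))

  peaks <- matrix(NA_real_, n_subj, 3,
                  dimnames = list(NULL, c("planning", "execution",
                                          "post")))
  power_rows <- list()
  dist_maps <- NULL
  conn <- list(planning = list(), execution = list(), post = list())
  for (s in seq_len(n_subj)) {
    idx <- which(epochs_all$trials$subject == s)
    ep <- subset_epochs(epochs_all, idx)
    tfr <- stage("tfr", morlet_tfr(ep, freqs = freqs, decim = decim))
    tfr <- stage("baseline", baseline_normalize(tfr))
    peaks[s, "planning"] <- peak_frequency(tfr, wins$planning,
                                           channels = plan_ch)$peak_hz
    peaks[s, "execution"] <- peak_frequency(tfr, wins$execution,
                                            channels = exec_ch)$peak_hz
    peaks[s, "post"] <- peak_frequency(tfr, wins$post)$peak_hz
    power_rows[[s]] <- data.frame(
      subject = s,
      broad_planning = band_average(tfr, bands$broad, wins$planning,
                                    plan_ch),
      broad_execution = band_average(tfr, bands$broad, wins$execution,
                                     exec_ch),
      high_execution = band_average(tfr, bands$high, wins$execution,
                                    exec_ch))
    # distance-wise execution-window maps for the cluster test
    subj_maps <- lapply(distances, function(D) {
      band_time_course(subset_tfr(tfr, which(tfr$trials$distance_cm == D)),
                       bands$broad, window = wins$execution)$power
    })
    if (is.null(dist_maps))
      dist_maps <- lapply(subj_maps, function(m)
        array(NA_real_, dim = c(n_subj, nrow(m), ncol(m))))
    for (di in seq_along(distances))
      dist_maps[[di]][s, , ] <- subj_maps[[di]]
    for (w in names(conn))
      conn[[w]][[s]] <- stage("connectivity",
                              wpli_matrix(ep, conn_band, wins[[w]]))
  }

  # --- peak-frequency statistics --------------------------------------
  fr <- friedman_test(peaks)
  report$peak_frequency <- list(
    mean_hz = as.list(colMeans(peaks)),
    friedman_chi2 = fr$chi2, friedman_p = fr$p,
    dunn = dunn_posthoc(peaks))

  # --- distance effect: cluster permutation ---------------------------
  clus <- stage("cluster", cluster_test(
    dist_maps, "rm_F", alpha_point = 0.001,
    neighbors = layout$neighbors, min_neighbors = 0, n_perm = n_perm,
    seed = seed + 2L))
  report$distance_cluster <- list(
    n_clusters = length(clus$clusters),
    max_mass = if (length(clus$clusters)) clus$clusters[[1]]$mass else 0,
    min_p = if (length(clus$clusters))
      min(vapply(clus$clusters, `[[`, numeric(1), "p")) else 1)

  # --- NBS ------------------------------------------------------------
  stacks <- lapply(conn, function(mats) conn_stack(mats)$edges)
  n_sub <- nrow(stacks[[1]])
  f_thr <- stats::qf(0.999, 2, (n_sub - 1) * 2)
  omni <- stage("nbs", nbs_test(stacks, "rm_F", threshold = f_thr,
                                n_perm = n_perm, seed = seed + 3L))
  if (is.null(nbs_threshold))
    nbs_threshold <- stats::qt(0.999, n_sub - 1)
  post_hoc <- stage("nbs", nbs_test(
    list(stacks$execution, stacks$planning), "paired_t",
    threshold = nbs_threshold, n_perm = n_perm, mode = "extent",
    alternative = "greater", seed = seed + 4L))
  comp_summary <- function(res) lapply(res$components, function(cm)
    list(n_edges = cm$n_edges, n_nodes = cm$n_nodes, p = cm$p,
         significant = cm$significant))
  report$nbs <- list(omnibus = comp_summary(omni),
                     exec_vs_plan = comp_summary(post_hoc))

  # --- regression screen ----------------------------------------------
  power_table <- do.call(rbind, power_rows)
  wpli_table <- data.frame(subject = seq_len(n_subj))
  if (length(post_hoc$components)) {
    comp <- post_hoc$components[[1]]
    wpli_table$wpli_exec_subnet <- vapply(conn$execution, subnetwork_mean,
                                          numeric(1),
                                          component = comp$pairs)
  }
  kin_subj <- stats::aggregate(cbind(pv = pv_cm_s, mt = mt_s) ~ subject,
                               data = kept, FUN = mean)
  screen <- stage("screen", gamma_kinematics_screen(
    power_table,
    if (ncol(wpli_table) > 1) wpli_table else NULL,
    kin_subj, exclude_sd = NULL))
  report$screen <- screen

  # --- outputs --------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(kin, file.path(out_dir, "kinematics.csv"),
                     row.names = FALSE)
    for (w in names(conn))
      write_conn_tsv(Reduce(`+`, lapply(conn[[w]], `[[`, "W")) /
                       length(conn[[w]]),
                     file.path(out_dir, paste0("wpli_", w, ".tsv")))
    write_report_json(report, file.path(out_dir, "report.json"))
  }
  report
}
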
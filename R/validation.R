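# Simulation studies ----------------------------------------------------
#
# Calibration and recovery studies for the statistical machinery. These
# are first-class package functions so the analysis scripts, the test
# suite and the acceptance script all run the identical study code.

#' Family-wise error of the cluster permutation test under the null
#'
#' Simulates exchangeable two-condition data (both conditions iid
#' Gaussian across subjects, channels and bins), runs the paired-t
#' cluster permutation test on each simulated data set, and reports the
#' fraction of simulations in which any cluster reached p < `alpha`.
#' For a calibrated test this family-wise rejection rate should lie
#' within the exact binomial confidence interval around `alpha`.
#'
#' The pointwise gate is parametric alpha 0.001; the neighbour-count
#' gate is disabled here (`min_neighbors = 0`) because cluster mass is
#' then a continuous statistic and the permutation p-value is exact up
#' to Monte-Carlo error, which is what a calibration check needs.
#'
#' @param n_sims,n_perm Simulation and permutation counts.
#' @param n_subjects,n_ch,n_bins Data dimensions per simulation.
#' @param alpha Cluster-level alpha tested.
#' @param alpha_point Pointwise gating alpha.
#' @param min_neighbors Neighbour gate passed to [cluster_test()].
#' @param seed Integer seed.
#' @return List: `rate`, `n_rejected`, `n_sims`, `binom_ci` (exact 95%
#'   interval of the rate under the nominal alpha).
#' @export
simulate_cluster_fwe <- function(n_sims = 200, n_perm = 500,
                                 n_subjects = 15, n_ch = 20, n_bins = 30,
                                 alpha = 0.05, alpha_point = 0.001,
                                 min_neighbors = 0, seed = 1L) {
  layout <- gen_layout(n_ch, seed = seed)
  rejected <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(seed * 100000L + s)
    a <- array(stats::rnorm(n_subjects * n_ch * n_bins),
               dim = c(n_subjects, n_ch, n_bins))
    b <- array(stats::rnorm(n_subjects * n_ch * n_bins),
               dim = c(n_subjects, n_ch, n_bins))
    res <- cluster_test(list(a, b), "paired_t",
                        alpha_point = alpha_point,
                        neighbors = layout$neighbors,
                        min_neighbors = min_neighbors, n_perm = n_perm,
                        alpha_cluster = alpha, seed = seed * 7L + s)
    rejected[s] <- length(res$clusters) > 0 &&
      any(vapply(res$clusters, `[[`, numeric(1), "p") < alpha)
  }
  list(rate = mean(rejected), n_rejected = sum(rejected),
       n_sims = n_sims,
       binom_ci = stats::qbinom(c(0.025, 0.975), n_sims, alpha) / n_sims)
}

#' Family-wise error of NBS under the global null
#'
#' Exchangeable null connectivity stacks (iid Gaussian edges in both
#' conditions), paired-t NBS with a one-sided primary threshold at the
#' pointwise 0.001 quantile; reports the fraction of simulations with
#' any significant component. Uses intensity (summed-statistic)
#' component size: with sparse suprathreshold graphs the edge-count size
#' is heavily tied at small integers and the test becomes conservative,
#' while the continuous intensity statistic makes the calibration check
#' sharp.
#'
#' @param n_sims,n_perm Simulation and permutation counts.
#' @param n_subjects,n_nodes Stack dimensions.
#' @param alpha Component-level alpha.
#' @param threshold Primary statistic cutoff; default the one-sided
#'   t quantile at pointwise alpha 0.001.
#' @param seed Integer seed.
#' @return List as in [simulate_cluster_fwe()].
#' @export
simulate_nbs_fwe <- function(n_sims = 200, n_perm = 500,
                             n_subjects = 15, n_nodes = 30,
                             alpha = 0.05,
                             threshold = stats::qt(0.999, n_subjects - 1),
                             seed = 1L) {
  n_edges <- n_nodes * (n_nodes - 1) / 2
  rejected <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(seed * 200000L + s)
    a <- matrix(stats::rnorm(n_subjects * n_edges), n_subjects)
    b <- matrix(stats::rnorm(n_subjects * n_edges), n_subjects)
    res <- nbs_test(list(b, a), "paired_t", threshold = threshold,
                    n_perm = n_perm, alpha = alpha, mode = "intensity",
                    alternative = "greater", seed = seed * 11L + s)
    rejected[s] <- any(vapply(res$components, `[[`, logical(1),
                              "significant"))
  }
  list(rate = mean(rejected), n_rejected = sum(rejected),
       n_sims = n_sims,
       binom_ci = stats::qbinom(c(0.025, 0.975), n_sims, alpha) / n_sims)
}

#' Recovery of a planted subnetwork difference by NBS
#'
#' Plants a clique-shaped condition difference (effect size `d` per
#' edge, in units of the difference SD) on `n_planted_nodes` nodes of an
#' otherwise exchangeable network, runs paired-t NBS (one-sided primary
#' threshold at the pointwise 0.001 quantile, extent mode), and scores a
#' simulation as success when a significant (p < alpha) component covers
#' at least `coverage` of the planted edges.
#'
#' @inheritParams simulate_nbs_fwe
#' @param n_planted_nodes Planted clique size (its edges carry the
#'   effect).
#' @param d Per-edge effect size.
#' @param coverage Required fraction of planted edges recovered.
#' @return List: `rate`, `mean_coverage`, `n_sims`.
#' @export
simulate_nbs_power <- function(n_sims = 50, n_perm = 500,
                               n_subjects = 15, n_nodes = 30,
                               n_planted_nodes = 8, d = 1.5,
                               alpha = 0.05, coverage = 0.8,
                               threshold = stats::qt(0.999,
                                                     n_subjects - 1),
                               seed = 1L) {
  n_edges <- n_nodes * (n_nodes - 1) / 2
  pairs <- upper_pairs(n_nodes)
  planted <- which(pairs[, 1] <= n_planted_nodes &
                     pairs[, 2] <= n_planted_nodes)
  success <- logical(n_sims)
  cov <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(seed * 300000L + s)
    a <- matrix(stats::rnorm(n_subjects * n_edges), n_subjects)
    delta <- matrix(stats::rnorm(n_subjects * n_edges), n_subjects)
    delta[, planted] <- delta[, planted] + d
    b <- a + delta
    res <- nbs_test(list(b, a), "paired_t", threshold = threshold,
                    n_perm = n_perm, alpha = alpha, mode = "extent",
                    alternative = "greater", seed = seed * 13L + s)
    best <- 0
    for (cm in res$components) {
      if (!cm$significant) next
      best <- max(best, length(intersect(cm$edges, planted)) /
                    length(planted))
    }
    cov[s] <- best
    success[s] <- best >= coverage
  }
  list(rate = mean(success), mean_coverage = mean(cov), n_sims = n_sims)
}

#' Fixed-slope recovery of the extent mixed model
#'
#' Replicated cohorts from [gen_lmm_cohort()] with known standardized
#' fixed slopes and per-subject random intercepts and slopes; each
#' cohort is fit with both random structures and the recovered fixed
#' slopes and the BIC preference are collected.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_subjects,n_trials Cohort size.
#' @param beta_pv,beta_mt Generating standardized fixed slopes.
#' @param sd_intercept,sd_slope,resid_sd Generating random-effect and
#'   residual SDs.
#' @param seed Integer seed.
#' @return List: `mean_pv_slope`, `mean_mt_slope`,
#'   `bic_prefer_slope_rate`, `per_rep` data.frame.
#' @export
simulate_lmm_recovery <- function(n_reps = 20, n_subjects = 40,
                                  n_trials = 60, beta_pv = 1.0,
                                  beta_mt = 0.7, sd_intercept = 0.2,
                                  sd_slope = 0.3, resid_sd = 0.2,
                                  seed = 1L) {
  rows <- lapply(seq_len(n_reps), function(rep) {
    d <- gen_lmm_cohort(n_subjects, n_trials, beta_pv, beta_mt,
                        sd_intercept = sd_intercept, sd_slope = sd_slope,
                        resid_sd = resid_sd, seed = seed * 1000L + rep)
    cmp <- compare_lmm(d$extent, d$pv, d$mt, d$subject)
    fx <- cmp$fit_slope$fixed_effects
    data.frame(rep = rep,
               pv_slope = fx$slope[fx$term == "pv"],
               mt_slope = fx$slope[fx$term == "mt"],
               bic_prefers_slope = cmp$preferred == "intercept+slope",
               lrt_p = cmp$lrt_p)
  })
  per_rep <- do.call(rbind, rows)
  list(mean_pv_slope = mean(per_rep$pv_slope),
       mean_mt_slope = mean(per_rep$mt_slope),
       bic_prefer_slope_rate = mean(per_rep$bic_prefers_slope),
       per_rep = per_rep)
}

#' Sign-pattern recovery of the regression screen
#'
#' Replicate cohorts from [gen_subject_summaries()] in which the gamma
#' burst gain is coupled to peak velocity (log-scale correlation `r`)
#' and movement time covaries negatively with peak velocity. A replicate
#' is a success when every power summary has a positive and significant
#' (p < 0.05) slope for peak velocity and a negative slope for movement
#' time.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_subjects Cohort size.
#' @param r Gain to peak-velocity coupling.
#' @param seed Integer seed.
#' @return List: `rate`, `per_rep` data.frame of the checked slopes.
#' @export
simulate_screen_signs <- function(n_reps = 20, n_subjects = 60, r = 0.6,
                                  seed = 1L) {
  rows <- lapply(seq_len(n_reps), function(rep) {
    tabs <- gen_subject_summaries(n_subjects, r = r,
                                  seed = seed * 2000L + rep)
    scr <- gamma_kinematics_screen(tabs$power, tabs$wpli, tabs$kin,
                                   exclude_sd = NULL)
    pw <- scr[scr$source == "power", ]
    pv <- pw[pw$outcome == "pv", ]
    mt <- pw[pw$outcome == "mt", ]
    data.frame(rep = rep,
               min_pv_beta = min(pv$beta), max_pv_p = max(pv$p),
               max_mt_beta = max(mt$beta),
               success = all(pv$beta > 0 & pv$p < 0.05) &&
                 all(mt$beta < 0))
  })
  per_rep <- do.call(rbind, rows)
  list(rate = mean(per_rep$success), per_rep = per_rep)
}
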
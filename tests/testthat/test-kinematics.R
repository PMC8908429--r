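noiseless_trial <- function(D = 10, T_mov = 0.5, rt = 0.3,
                            target_onset = 0.5, fs = 200) {
  cfg <- synth_config(traj_noise_cm = 0, fs_tablet = fs)
  make_trajectory <- getFromNamespace("make_trajectory", "gammareach")
  make_trajectory(D, 1, rt, T_mov, target_onset, cfg, noise_sd = 0)
}

test_that("zero-phase Butterworth keeps DC and rejects high frequency", {
  fs <- 200
  const <- data.frame(t = seq(0, 2, by = 1 / fs), x = 3, y = -1)
  out <- filter_trajectory(const, fs)
  expect_equal(out$x, const$x, tolerance = 1e-6)
  expect_equal(out$y, const$y, tolerance = 1e-6)

  t <- seq(0, 4, by = 1 / fs)
  xy <- data.frame(t = t, x = sin(2 * pi * 2 * t) + sin(2 * pi * 50 * t),
                   y = 0)
  filt <- filter_trajectory(xy, fs, cutoff = 10)
  amp <- function(v, f) {
    sp <- Mod(stats::fft(v))
    sp[which.min(abs(seq(0, fs, length.out = length(v) + 1)[-1] - f)) + 0]
  }
  n <- length(t)
  fgrid <- (seq_len(n) - 1) * fs / n
  amp_at <- function(v, f) Mod(stats::fft(v))[which.min(abs(fgrid - f))]
  expect_gt(amp_at(xy$x, 2) / amp_at(filt$x, 2), 0.95)
  expect_lt(amp_at(filt$x, 2) / amp_at(xy$x, 2), 1.05)
  expect_lt(amp_at(filt$x, 50) / amp_at(xy$x, 50), 0.1)   # > 20 dB down

  expect_error(filter_trajectory(xy, fs, cutoff = 120), "Nyquist")
  expect_error(filter_trajectory(xy[1:5, ], fs), "too short")
})

test_that("derivatives recover analytic speed and acceleration", {
  fs <- 200
  t <- seq(0, 2, by = 1 / fs)
  lin <- data.frame(x = 3 * t, y = 4 * t)          # speed 5
  d <- differentiate(lin, fs)
  expect_equal(d$speed, rep(5, length(t)), tolerance = 1e-8)
  expect_equal(max(abs(d$accel[3:(length(t) - 2)])), 0, tolerance = 1e-6)

  r <- 2; w <- 2 * pi * 0.5                        # circle, v = r w
  circ <- data.frame(x = r * cos(w * t), y = r * sin(w * t))
  dc <- differentiate(circ, fs)
  inner <- 3:(length(t) - 2)
  expect_equal(dc$speed[inner], rep(r * w, length(inner)),
               tolerance = 1e-3)

  mj <- noiseless_trial()
  dm <- differentiate(mj, fs)
  expect_equal(max(dm$speed), 1.875 * 10 / 0.5, tolerance = 0.01)

  expect_error(differentiate(lin[1:3, ], fs), "4 samples")
})

test_that("segmentation recovers generative measures on noiseless trials", {
  fs <- 200
  traj <- noiseless_trial(D = 10, T_mov = 0.5, rt = 0.3)
  res <- segment_and_summarize(traj, target_onset = 0.5, fs = fs)
  expect_true(res$valid)
  # back-walked onset lands on the true onset within two samples
  expect_lt(abs(res$rt_s - 0.3), 2.5 / fs)
  expect_equal(res$extent_cm, 10, tolerance = 0.01)
  expect_equal(res$pv_cm_s, 37.5, tolerance = 0.01 * 37.5)
  # peak velocity at mid-movement
  expect_lt(abs(res$pv_t_s + res$rt_s - 0.3 - 0.25), 0.01)

  flat <- data.frame(t = seq(0, 3, by = 1 / fs), x = 0, y = 0)
  flat$x <- flat$x + stats::rnorm(nrow(flat), 0, 1e-9)
  res2 <- segment_and_summarize(flat, 0.5, fs)
  expect_true(is.data.frame(res2))   # flagged, not an error
})

test_that("2-SD rejection removes exactly the rule-violating trials", {
  set.seed(1)
  n <- 50
  tab <- data.frame(subject = 1, rt_s = rnorm(n, 0.3, 0.01),
                    mt_s = rnorm(n, 0.4, 0.01),
                    tmt_s = rnorm(n, 0.8, 0.01),
                    pv_cm_s = rnorm(n, 30, 1))
  tab$pv_cm_s[7] <- mean(tab$pv_cm_s[-7]) + 5 * sd(tab$pv_cm_s[-7])
  res <- reject_outliers(tab, k_sd = 2)
  expect_true(7 %in% res$rejected)
  # the rejected set is exactly the set violating the original-mean rule
  viol <- rep(FALSE, n)
  for (m in c("rt_s", "mt_s", "tmt_s", "pv_cm_s")) {
    v <- tab[[m]]
    viol <- viol | abs(v - mean(v)) > 2 * sd(v)
  }
  expect_identical(res$rejected, which(viol))

  ident <- data.frame(subject = 1, rt_s = rep(0.3, 5), mt_s = 0.4,
                      tmt_s = 0.8, pv_cm_s = 30)
  expect_length(reject_outliers(ident)$rejected, 0)   # zero-SD convention
  expect_identical(reject_outliers(tab, k_sd = Inf)$kept, tab)
  expect_error(reject_outliers(tab[0, ]), "empty")
})

test_that("mixed model recovers noiseless slopes and matches the two-stage oracle", {
  set.seed(2)
  n_s <- 12; n_t <- 30
  subject <- rep(seq_len(n_s), each = n_t)
  pv <- rnorm(n_s * n_t); mt <- rnorm(n_s * n_t)
  extent <- 1.0 * pv + 0.7 * mt
  fit <- fit_lmm(extent, pv, mt, subject, random = "intercept")
  fx <- fit$fixed_effects
  # z-scoring rescales each slope by the sample SD ratio
  expect_equal(fx$slope[fx$term == "pv"], 1.0 * sd(pv) / sd(extent),
               tolerance = 1e-6)
  expect_equal(fx$slope[fx$term == "mt"], 0.7 * sd(mt) / sd(extent),
               tolerance = 1e-6)
  expect_gt(fit$r2_adjusted, 0.9999)
  expect_true(all(fx$ci_lo <= fx$slope & fx$slope <= fx$ci_hi))

  d <- gen_lmm_cohort(n_subjects = 20, n_trials = 40, seed = 3)
  f2 <- fit_lmm(d$extent, d$pv, d$mt, d$subject)
  oracle <- two_stage_ols(d$extent, d$pv, d$mt, d$subject)
  fx2 <- f2$fixed_effects
  expect_equal(fx2$slope[fx2$term == "pv"], unname(oracle["pv"]),
               tolerance = 0.05)
  expect_equal(fx2$slope[fx2$term == "mt"], unname(oracle["mt"]),
               tolerance = 0.05)
})

test_that("random-slope variance is detected by BIC and absent under the null", {
  d <- gen_lmm_cohort(n_subjects = 30, n_trials = 40, sd_slope = 0.3,
                      seed = 4)
  cmp <- compare_lmm(d$extent, d$pv, d$mt, d$subject)
  expect_lt(cmp$bic_slope, cmp$bic_intercept)
  expect_identical(cmp$preferred, "intercept+slope")

  # TLRT under the null (no slope variance): p should not be
  # anti-conservative; boundary truncation makes it conservative
  n_sims <- 40
  ps <- vapply(seq_len(n_sims), function(i) {
    d0 <- gen_lmm_cohort(n_subjects = 10, n_trials = 12, sd_slope = 0,
                         resid_sd = 0.5, seed = 100 + i)
    suppressMessages(suppressWarnings(
      compare_lmm(d0$extent, d0$pv, d0$mt, d0$subject)))$lrt_p
  }, numeric(1))
  expect_lte(mean(ps < 0.05),
             0.05 + 1.96 * sqrt(0.05 * 0.95 / n_sims))
})
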
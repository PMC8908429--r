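#' Zero-phase Butterworth low-pass filter of a trajectory
#'
#' Applies a forward-backward (zero-phase) low-pass Butterworth filter to
#' each coordinate of a planar trajectory. Defaults: order 4, cutoff
#' 10 Hz, the usual choices for tablet reaching data.
#'
#' @param xy data.frame or matrix with columns x, y (a `t` column, if
#'   present, is passed through untouched).
#' @param fs Sampling rate, Hz.
#' @param cutoff Low-pass cutoff, Hz; must be < fs/2.
#' @param order Filter order.
#' @return Same shape as `xy`, filtered.
#' @export
filter_trajectory <- function(xy, fs, cutoff = 10, order = 4) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist rate fs/2")
  xy <- as.data.frame(xy)
  n <- nrow(xy)
  if (n < 3 * order) stop("trajectory too short for the filter order")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # endpoint-reflected padding suppresses the filter's edge transients
  np <- min(n - 1, max(3 * order, ceiling(5 * fs / cutoff)))
  for (col in intersect(c("x", "y"), names(xy))) {
    v <- xy[[col]]
    vp <- c(2 * v[1] - v[(np + 1):2], v,
            2 * v[n] - v[(n - 1):(n - np)])
    xy[[col]] <- as.numeric(signal::filtfilt(bf, vp))[np + seq_len(n)]
  }
  xy
}

#' Tangential speed, acceleration and jerk of a planar trajectory
#'
#' First, second and third derivatives of the path: speed is the norm of
#' the coordinate-wise first derivative; acceleration and jerk are the
#' derivatives of speed. Central differences in the interior, one-sided
#' at the edges.
#'
#' @param xy data.frame or matrix with columns x, y.
#' @param fs Sampling rate, Hz.
#' @return data.frame(speed, accel, jerk), same length as the input.
#' @export
differentiate <- function(xy, fs) {
  xy <- as.data.frame(xy)
  if (nrow(xy) < 4) stop("need at least 4 samples")
  vx <- finite_diff(xy$x, fs)
  vy <- finite_diff(xy$y, fs)
  speed <- sqrt(vx^2 + vy^2)
  accel <- finite_diff(speed, fs)
  jerk <- finite_diff(accel, fs)
  data.frame(speed = speed, accel = accel, jerk = jerk)
}

finite_diff <- function(v, fs) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * fs / 2
  d[1] <- (v[2] - v[1]) * fs
  d[n] <- (v[n] - v[n - 1]) * fs
  d
}

#' Segment one trial and extract its kinematic measures
#'
#' Movement onset is the first sample after target onset whose speed
#' exceeds `onset_frac` of the trial's peak speed and stays above it for
#' at least `sustain_s`, then walked back along the decreasing speed
#' flank to the start of the rise (where speed drops below 0.5% of the
#' peak or stops decreasing) — the usual correction for the systematic
#' delay of a pure threshold crossing. The movement offset is found
#' symmetrically from the end. The out-going segment ends at the
#' reversal (maximum radial distance from the start position); extent is
#' that maximum radial distance, and peak velocity and its timing are
#' taken on the out-going segment.
#'
#' @param traj Filtered trajectory data.frame with columns t, x, y.
#' @param target_onset Time of target appearance (s, on the trajectory
#'   clock).
#' @param fs Sampling rate, Hz.
#' @param onset_frac Speed threshold as a fraction of peak speed.
#' @param sustain_s Minimum time the speed must stay above threshold.
#' @return One-row data.frame: rt_s, mt_s, tmt_s, pv_cm_s, pv_t_s,
#'   extent_cm, valid (FALSE when the speed never crosses the threshold;
#'   measures are NA then, the trial is flagged, not dropped).
#' @export
segment_and_summarize <- function(traj, target_onset, fs,
                                  onset_frac = 0.05, sustain_s = 0.02) {
  sp <- differentiate(traj, fs)$speed
  t <- traj$t
  after <- which(t >= target_onset)
  peak_all <- max(sp[after])
  thr <- onset_frac * peak_all
  sustain_n <- max(1L, round(sustain_s * fs))
  above <- sp > thr
  onset_i <- find_sustained(above, after[1], sustain_n, forward = TRUE)
  if (is.na(onset_i))
    return(data.frame(rt_s = NA_real_, mt_s = NA_real_, tmt_s = NA_real_,
                      pv_cm_s = NA_real_, pv_t_s = NA_real_,
                      extent_cm = NA_real_, valid = FALSE))
  onset_i <- walk_to_rise(sp, onset_i, after[1], 0.005 * peak_all,
                          forward = TRUE)
  offset_i <- find_sustained(above, length(t), sustain_n, forward = FALSE)
  if (is.na(offset_i) || offset_i <= onset_i) offset_i <- length(t)
  offset_i <- walk_to_rise(sp, offset_i, length(t), 0.005 * peak_all,
                           forward = FALSE)

  x0 <- traj$x[onset_i]; y0 <- traj$y[onset_i]
  rad <- sqrt((traj$x - x0)^2 + (traj$y - y0)^2)
  seg <- onset_i:offset_i
  rev_i <- seg[which.max(rad[seg])]
  out_seg <- onset_i:rev_i
  pv_i <- out_seg[which.max(sp[out_seg])]

  data.frame(rt_s = t[onset_i] - target_onset,
             mt_s = t[rev_i] - t[onset_i],
             tmt_s = t[offset_i] - t[onset_i],
             pv_cm_s = sp[pv_i],
             pv_t_s = t[pv_i] - t[onset_i],
             extent_cm = max(rad[seg]),
             valid = TRUE)
}

# Walk from a threshold crossing back (forward = TRUE) or forward along
# the speed flank to the start/end of the rise: stop where the speed
# stops decreasing or falls below `floor_speed`.
walk_to_rise <- function(sp, i, limit, floor_speed, forward = TRUE) {
  step <- if (forward) -1L else 1L
  while (i != limit &&
         sp[i + step] < sp[i] && sp[i + step] > floor_speed)
    i <- i + step
  if (i != limit && sp[i + step] <= floor_speed) i <- i + step
  i
}

# First index (from `start`, scanning forward/backward) where `above`
# holds for `sustain_n` consecutive samples; NA when never.
find_sustained <- function(above, start, sustain_n, forward = TRUE) {
  n <- length(above)
  idx <- if (forward) start:n else start:1
  run <- 0L
  for (i in idx) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= sustain_n) return(if (forward) i - sustain_n + 1L
                                 else i + sustain_n - 1L)
  }
  NA_integer_
}

#' Kinematic measures for a whole batch of generated trials
#'
#' Filters, differentiates and segments every trajectory of a
#' [gen_reach_trials()] result and binds the per-trial measures to the
#' trial table.
#'
#' @param reaches List from [gen_reach_trials()].
#' @param cfg The `synth_config` used to generate them (for the tablet
#'   rate).
#' @param cutoff,order Butterworth settings passed to
#'   [filter_trajectory()].
#' @return Trial table with appended kinematic columns.
#' @export
kinematics_table <- function(reaches, cfg, cutoff = 10, order = 4) {
  fs <- cfg$fs_tablet
  meas <- lapply(seq_along(reaches$trajectories), function(i) {
    tr <- filter_trajectory(reaches$trajectories[[i]], fs, cutoff, order)
    segment_and_summarize(tr, reaches$trials$target_onset_s[i], fs)
  })
  cbind(reaches$trials, do.call(rbind, meas))
}

#' Per-subject 2-SD outlier rejection
#'
#' Rejects, within each subject, every trial for which ANY of the listed
#' measures deviates from that subject's mean by more than `k_sd`
#' standard deviations. A zero-SD measure rejects nothing. Rejection is
#' decided against the original (pre-rejection) mean and SD.
#'
#' @param table Per-trial table with a `subject` column.
#' @param k_sd SD multiplier (the conventional criterion is 2).
#' @param measures Columns screened.
#' @return List with `kept` (table subset), `rejected` (row indices of
#'   the input that were rejected).
#' @export
reject_outliers <- function(table, k_sd = 2,
                            measures = c("rt_s", "mt_s", "tmt_s",
                                         "pv_cm_s")) {
  if (nrow(table) == 0) stop("empty trial table")
  missing <- setdiff(measures, names(table))
  if (length(missing)) stop("missing measure column(s): ",
                            paste(missing, collapse = ", "))
  bad <- rep(FALSE, nrow(table))
  for (s in unique(table$subject)) {
    rows <- which(table$subject == s)
    if (length(rows) < 3) stop("need >= 3 trials per subject")
    for (m in measures) {
      v <- table[[m]][rows]
      mu <- mean(v, na.rm = TRUE); sd_v <- stats::sd(v, na.rm = TRUE)
      if (is.na(sd_v) || sd_v == 0) next
      bad[rows] <- bad[rows] | (!is.na(v) & abs(v - mu) > k_sd * sd_v)
    }
    if (!is.null(table$valid))
      bad[rows] <- bad[rows] | is.na(table$valid[rows]) |
        !table$valid[rows]
  }
  list(kept = table[!bad, , drop = FALSE], rejected = which(bad))
}

#' Mixed-effects model of movement extent
#'
#' Fits extent ~ peak velocity + movement time with subjects as the
#' random factor, by REML, after z-transforming all three variables.
#' `random = "intercept"` fits a per-subject random intercept;
#' `"intercept+slope"` adds correlated per-subject random slopes for both
#' predictors. Model comparison metrics (BIC, log-likelihood, and the
#' likelihood-ratio test of the two random structures) are computed from
#' maximum-likelihood refits.
#'
#' @param extent,pv,mt Per-trial vectors.
#' @param subject Per-trial subject identifier.
#' @param random `"intercept"` or `"intercept+slope"`.
#' @return An object of class `lmm_fit`: fixed-effect table
#'   (slope, SE, t, df, p, 95% CI), `r2_adjusted` (conditional, from
#'   fitted values including random effects), `bic` and `loglik` (ML),
#'   `singular` flag, and the underlying `model`.
#' @export
fit_lmm <- function(extent, pv, mt, subject,
                    random = c("intercept+slope", "intercept")) {
  random <- match.arg(random)
  if (length(unique(subject)) < 2) stop("need >= 2 subjects")
  d <- data.frame(extent = as.numeric(scale(extent)),
                  pv = as.numeric(scale(pv)),
                  mt = as.numeric(scale(mt)),
                  subject = factor(subject))
  form <- if (random == "intercept")
    extent ~ pv + mt + (1 | subject)
  else
    extent ~ pv + mt + (1 + pv + mt | subject)
  fit <- lmerTest::lmer(form, data = d, REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE))
  co <- stats::coef(summary(fit))
  rows <- c("pv", "mt")
  fixed <- data.frame(term = rows,
                      slope = co[rows, "Estimate"],
                      se = co[rows, "Std. Error"],
                      t = co[rows, "t value"],
                      df = co[rows, "df"],
                      p = co[rows, "Pr(>|t|)"],
                      row.names = NULL)
  fixed$ci_lo <- fixed$slope - stats::qt(0.975, fixed$df) * fixed$se
  fixed$ci_hi <- fixed$slope + stats::qt(0.975, fixed$df) * fixed$se

  # conditional R^2 (fitted values include the random effects), adjusted
  # for the number of fixed-effect parameters, matching the usual
  # "variance explained" usage for these models
  res <- d$extent - stats::fitted(fit)
  n <- nrow(d); p_fix <- 3
  r2 <- 1 - sum(res^2) / sum((d$extent - mean(d$extent))^2)
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p_fix)

  ml <- stats::update(fit, REML = FALSE)
  ll <- stats::logLik(ml)
  structure(list(fixed_effects = fixed, random = random,
                 r2_adjusted = r2_adj,
                 bic = stats::BIC(ml),
                 loglik = as.numeric(ll),
                 ml_df = attr(ll, "df"),
                 singular = lme4::isSingular(fit),
                 model = fit),
            class = "lmm_fit")
}

#' Compare the two random structures of the extent model
#'
#' Fits the random-intercept and random-intercept-plus-slope models and
#' reports BIC for both plus the likelihood-ratio test (chi-square with
#' df = difference in parameter count; the boundary issue of testing
#' variance components at zero is flagged, not corrected).
#'
#' @inheritParams fit_lmm
#' @return List: `fit_intercept`, `fit_slope` (both `lmm_fit`),
#'   `bic_intercept`, `bic_slope`, `lrt_chisq`, `lrt_df`, `lrt_p`,
#'   `preferred` ("intercept" or "intercept+slope" by BIC),
#'   `boundary_note`.
#' @export
compare_lmm <- function(extent, pv, mt, subject) {
  f0 <- fit_lmm(extent, pv, mt, subject, random = "intercept")
  f1 <- fit_lmm(extent, pv, mt, subject, random = "intercept+slope")
  chisq <- max(0, 2 * (f1$loglik - f0$loglik))
  df <- f1$ml_df - f0$ml_df
  list(fit_intercept = f0, fit_slope = f1,
       bic_intercept = f0$bic, bic_slope = f1$bic,
       lrt_chisq = chisq, lrt_df = df,
       lrt_p = stats::pchisq(chisq, df, lower.tail = FALSE),
       preferred = if (f1$bic < f0$bic) "intercept+slope" else "intercept",
       boundary_note = paste("variance components tested on the boundary;",
                             "chi-square p is conservative"))
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> random: %s  R2adj(conditional) = %.3f  BIC = %.1f%s\n",
              x$random, x$r2_adjusted, x$bic,
              if (x$singular) "  [singular fit]" else ""))
  print(x$fixed_effects, digits = 3)
  invisible(x)
}
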
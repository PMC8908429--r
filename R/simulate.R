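#' Configuration of the synthetic reaching + EEG generator
#'
#' Bundles every tunable of the generator: task geometry (three target
#' distances, eight directions), sampling rates, the epoch window around
#' movement onset, the two gamma bursts (a pre-movement planning burst and
#' an execution burst whose envelope tracks the movement speed profile),
#' optional phase-lagged coupling between channel pairs, zero-lag
#' neighbour mixing emulating volume conduction, and the 1/f background.
#'
#' Burst amplitudes scale with target distance through `gains` (one gain
#' per distance, nondecreasing) and with a per-subject lognormal gain
#' multiplier that creates between-subject variability. The per-subject
#' multiplier is correlated (on the log scale, correlation `gain_pv_r`)
#' with the subject's peak-velocity level, so that cohorts carry a
#' recoverable brain-behaviour coupling.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_trials_per_distance Trials per target distance per subject
#'   (the task has 3 distances x 8 directions).
#' @param distances_cm Target distances in cm, strictly increasing.
#' @param fs_eeg EEG sampling rate, Hz.
#' @param fs_tablet Tablet (trajectory) sampling rate, Hz.
#' @param epoch_window_s Epoch limits in seconds relative to movement
#'   onset.
#' @param burst_plan,burst_exec Lists describing the two injected bursts:
#'   `freq` (carrier, Hz), `window` (seconds relative to movement onset),
#'   `region` (scalp region receiving the burst), `gains` (amplitude
#'   multiplier per distance), `amp` (base amplitude in noise-SD units).
#' @param coupling_edges List of coupling specs, each a list with `i`,
#'   `j` (channel indices), `lag` (phase lag in radians, in (0, pi)),
#'   `freq` (Hz) and `amp`.
#' @param coupling_window Seconds; window in which coupled components are
#'   active.
#' @param mixing_gain Zero-lag leakage: each channel receives this
#'   fraction of the mean of its neighbours.
#' @param noise_exponent Spectral exponent of the 1/f background.
#' @param noise_sd Background noise SD per channel.
#' @param rt_mean_s Mean reaction time per distance (s); the task shows
#'   shorter reaction times for farther targets.
#' @param rt_sd_s,rt_min_s Reaction-time spread and truncation floor (s).
#' @param mt_a_s,mt_b_s_per_cm Movement time model T = a + b D, so that
#'   peak velocity (1.875 D / T), not duration, carries most of the
#'   extent scaling.
#' @param mt_cv Lognormal trial-to-trial jitter SD of movement time.
#' @param traj_noise_cm Gaussian sensor noise on the tablet coordinates.
#' @param subject_gain_sd Lognormal sigma of the per-subject burst gain.
#' @param gain_pv_r Log-scale correlation between subject burst gain and
#'   subject peak-velocity level.
#' @param seed Integer seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8,
                         n_trials_per_distance = 32,
                         distances_cm = c(4, 7, 10),
                         fs_eeg = 250,
                         fs_tablet = 200,
                         epoch_window_s = c(-1, 2.5),
                         burst_plan = list(freq = 54,
                                           window = c(-0.152, -0.052),
                                           region = "centro-parietal",
                                           gains = c(1.0, 1.3, 1.6),
                                           amp = 0.8),
                         burst_exec = list(freq = 66,
                                           window = c(0.052, 0.500),
                                           region = "parieto-occipital",
                                           gains = c(1.0, 1.3, 1.6),
                                           amp = 1.0),
                         coupling_edges = list(),
                         coupling_window = c(0.052, 0.500),
                         mixing_gain = 0,
                         noise_exponent = 1.0,
                         noise_sd = 1.0,
                         rt_mean_s = c(0.370, 0.350, 0.330),
                         rt_sd_s = 0.060,
                         rt_min_s = 0.150,
                         mt_a_s = 0.250,
                         mt_b_s_per_cm = 0.015,
                         mt_cv = 0.05,
                         traj_noise_cm = 0.01,
                         subject_gain_sd = 0.2,
                         gain_pv_r = 0.6,
                         seed = 1L) {
  cfg <- list(n_subjects = n_subjects,
              n_trials_per_distance = n_trials_per_distance,
              distances_cm = distances_cm, fs_eeg = fs_eeg,
              fs_tablet = fs_tablet, epoch_window_s = epoch_window_s,
              burst_plan = burst_plan, burst_exec = burst_exec,
              coupling_edges = coupling_edges,
              coupling_window = coupling_window,
              mixing_gain = mixing_gain, noise_exponent = noise_exponent,
              noise_sd = noise_sd, rt_mean_s = rt_mean_s,
              rt_sd_s = rt_sd_s, rt_min_s = rt_min_s, mt_a_s = mt_a_s,
              mt_b_s_per_cm = mt_b_s_per_cm, mt_cv = mt_cv,
              traj_noise_cm = traj_noise_cm,
              subject_gain_sd = subject_gain_sd, gain_pv_r = gain_pv_r,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  d <- cfg$distances_cm
  if (any(diff(d) <= 0)) stop("distances_cm must be strictly increasing")
  for (b in list(cfg$burst_plan, cfg$burst_exec)) {
    if (length(b$gains) != length(d))
      stop("burst gains must give one value per distance")
    if (any(diff(b$gains) < 0))
      stop("burst gains per distance must be nondecreasing")
    if (b$freq >= cfg$fs_eeg / 2)
      stop("burst frequency ", b$freq, " Hz is at or above Nyquist (fs/2)")
  }
  for (ce in cfg$coupling_edges) {
    if (!(ce$lag > 0 && ce$lag < pi))
      stop("coupling phase lag must lie strictly in (0, pi)")
    if (ce$freq >= cfg$fs_eeg / 2)
      stop("coupling frequency at or above Nyquist")
  }
  if (length(cfg$rt_mean_s) != length(d))
    stop("rt_mean_s must give one value per distance")
  if (cfg$epoch_window_s[1] >= cfg$epoch_window_s[2])
    stop("epoch window must be increasing")
  invisible(cfg)
}

#' Minimum-jerk position and speed profiles
#'
#' The out-going segment of a reach follows the minimum-jerk path
#' x(tau) = D (10 tau^3 - 15 tau^4 + 6 tau^5) with tau = t/T, whose
#' tangential speed peaks at 1.875 D / T at t = T/2.
#'
#' @param t Time since movement onset (s); values outside [0, T] are
#'   clamped.
#' @param D Movement extent (cm), > 0.
#' @param T_mov Movement duration (s), > 0.
#' @return Position (cm) or speed (cm/s) along the path.
#' @export
min_jerk_pos <- function(t, D, T_mov) {
  if (D <= 0 || T_mov <= 0) stop("D and T_mov must be positive")
  tau <- pmin(pmax(t / T_mov, 0), 1)
  D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' @rdname min_jerk_pos
#' @export
min_jerk_speed <- function(t, D, T_mov) {
  if (D <= 0 || T_mov <= 0) stop("D and T_mov must be positive")
  tau <- t / T_mov
  v <- (D / T_mov) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  v[tau < 0 | tau > 1] <- 0
  v
}

# Per-subject latent table: lognormal burst-gain multiplier, correlated
# (log scale, r = gain_pv_r) with a peak-velocity multiplier; movement
# time is divided by the PV multiplier so PV and MT covary negatively.
gen_subjects <- function(cfg) {
  n <- cfg$n_subjects
  z_g <- stats::rnorm(n)
  r <- cfg$gain_pv_r
  z_pv <- r * z_g + sqrt(1 - r^2) * stats::rnorm(n)
  data.frame(subject = seq_len(n),
             gain_mult = exp(cfg$subject_gain_sd * z_g),
             pv_mult = exp(0.10 * z_pv),
             rt_shift = stats::rnorm(n, 0, 0.02))
}

#' Generate out-and-back reaching trials
#'
#' Simulates, per subject, `n_trials_per_distance` reaches to each of the
#' three target distances, cycling through the eight directions. Each
#' trajectory holds at the start position, then follows a minimum-jerk
#' out-going segment of duration T and a minimum-jerk return of 1.1 T,
#' sampled at the tablet rate with Gaussian coordinate noise. Reaction
#' time is truncated-normal with distance-specific means (shorter for
#' farther targets); movement time is T = a + b D with lognormal trial
#' jitter, divided by the subject's peak-velocity multiplier.
#'
#' @param cfg A `synth_config`.
#' @param seed Optional integer overriding `cfg$seed`.
#' @return A list with `trials` (one row per trial: subject, trial,
#'   distance_cm, distance_label, direction, target_onset_s and the
#'   generative ground truth rt_true_s, mt_true_s, pv_true_cm_s),
#'   `trajectories` (list of data.frames t, x, y) and `subjects` (the
#'   per-subject latent table).
#' @export
gen_reach_trials <- function(cfg, seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed else as.integer(seed))
  subjects <- gen_subjects(cfg)
  n_d <- length(cfg$distances_cm)
  rows <- list(); trajs <- list(); k <- 0L
  target_onset <- 0.5
  for (s in seq_len(cfg$n_subjects)) {
    for (di in seq_len(n_d)) {
      D <- cfg$distances_cm[di]
      for (tr in seq_len(cfg$n_trials_per_distance)) {
        k <- k + 1L
        direction <- ((tr - 1L) %% 8L) + 1L
        rt <- rt_truncnorm(1, cfg$rt_mean_s[di] + subjects$rt_shift[s],
                           cfg$rt_sd_s, cfg$rt_min_s)
        T_mov <- (cfg$mt_a_s + cfg$mt_b_s_per_cm * D) *
          exp(stats::rnorm(1, 0, cfg$mt_cv)) / subjects$pv_mult[s]
        trajs[[k]] <- make_trajectory(D, direction, rt, T_mov,
                                      target_onset, cfg)
        rows[[k]] <- data.frame(
          subject = s, trial = k, distance_cm = D,
          distance_label = c("short", "medium", "long")[di],
          direction = direction, target_onset_s = target_onset,
          rt_true_s = rt, mt_true_s = T_mov,
          pv_true_cm_s = 1.875 * D / T_mov)
      }
    }
  }
  list(trials = do.call(rbind, rows), trajectories = trajs,
       subjects = subjects)
}

rt_truncnorm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) {
    i <- x < lower
    x[i] <- stats::rnorm(sum(i), mean, sd)
  }
  x
}

make_trajectory <- function(D, direction, rt, T_mov, target_onset, cfg,
                            noise_sd = cfg$traj_noise_cm) {
  fs <- cfg$fs_tablet
  T_back <- 1.1 * T_mov
  total <- target_onset + rt + T_mov + T_back + 0.3
  t <- seq(0, total, by = 1 / fs)
  onset <- target_onset + rt
  s_rad <- numeric(length(t))
  out_ph <- t >= onset & t < onset + T_mov
  back_ph <- t >= onset + T_mov & t < onset + T_mov + T_back
  s_rad[out_ph] <- min_jerk_pos(t[out_ph] - onset, D, T_mov)
  s_rad[back_ph] <- D - min_jerk_pos(t[back_ph] - onset - T_mov, D, T_back)
  ang <- (direction - 1) * pi / 4
  x <- s_rad * cos(ang) + stats::rnorm(length(t), 0, noise_sd)
  y <- s_rad * sin(ang) + stats::rnorm(length(t), 0, noise_sd)
  data.frame(t = t, x = x, y = y)
}

# Spectrally shaped background: white noise whose amplitude spectrum is
# scaled by f^(-exponent/2), rescaled to the requested SD.
one_over_f_noise <- function(n, exponent = 1, sd = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)            # two-sided frequency index
  scale <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x * (sd / s)
}

gauss_envelope <- function(times, window) {
  center <- mean(window)
  fwhm <- diff(window)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(times - center)^2 / (2 * sigma^2))
}

#' Generate epoched EEG with injected gamma structure
#'
#' Builds trials x channels x time epochs at the EEG sampling rate,
#' time-locked to movement onset. Each trial is 1/f background noise per
#' channel, plus a Gaussian-windowed planning burst on the centro-parietal
#' channels (carrier `burst_plan$freq`), plus an execution burst on the
#' parieto-occipital channels whose envelope is the trial's out-and-back
#' speed profile (carrier `burst_exec$freq`). Burst amplitude is
#' `amp * gains[distance] * subject gain multiplier`. For each coupling
#' edge, a shared sinusoid with a fixed phase lag (and random phase per
#' trial) is added to the two channels during the coupling window; with
#' `mixing_gain > 0` each channel finally receives a zero-lag mixture of
#' its neighbours, emulating volume conduction.
#'
#' @param trials The list returned by [gen_reach_trials()] (or at least
#'   its `trials` and `subjects` elements).
#' @param layout A `reach_layout`.
#' @param cfg A `synth_config`.
#' @param seed Optional integer overriding `cfg$seed + 1`.
#' @return An object of class `eeg_epochs`: list with `data` (trials x
#'   channels x time array), `times`, `fs`, `ch_names`, `trials` (the
#'   trial table).
#' @export
gen_eeg_epochs <- function(trials, layout, cfg, seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed + 1L else as.integer(seed))
  validate_synth_config(cfg)
  tab <- trials$trials
  subjects <- trials$subjects
  fs <- cfg$fs_eeg
  times <- seq(cfg$epoch_window_s[1], cfg$epoch_window_s[2], by = 1 / fs)
  n_t <- length(times)
  n_ch <- length(layout$names)
  n_tr <- nrow(tab)
  data <- array(0, dim = c(n_tr, n_ch, n_t))

  plan_ch <- which(layout$region == cfg$burst_plan$region)
  exec_ch <- which(layout$region == cfg$burst_exec$region)
  plan_env <- gauss_envelope(times, cfg$burst_plan$window)
  d_index <- match(tab$distance_cm, cfg$distances_cm)
  coup_env <- gauss_envelope(times, cfg$coupling_window)

  for (tr in seq_len(n_tr)) {
    gm <- if (!is.null(subjects)) subjects$gain_mult[tab$subject[tr]] else 1
    for (ch in seq_len(n_ch))
      data[tr, ch, ] <- one_over_f_noise(n_t, cfg$noise_exponent,
                                         cfg$noise_sd)
    # planning burst
    amp_p <- cfg$burst_plan$amp * cfg$burst_plan$gains[d_index[tr]] * gm
    if (amp_p > 0 && length(plan_ch)) {
      carrier <- cos(2 * pi * cfg$burst_plan$freq * times +
                       stats::runif(1, 0, 2 * pi))
      sig <- amp_p * plan_env * carrier
      for (ch in plan_ch) data[tr, ch, ] <- data[tr, ch, ] + sig
    }
    # execution burst: envelope follows the out-and-back speed profile
    amp_e <- cfg$burst_exec$amp * cfg$burst_exec$gains[d_index[tr]] * gm
    if (amp_e > 0 && length(exec_ch)) {
      T_mov <- tab$mt_true_s[tr]; T_back <- 1.1 * T_mov
      env <- min_jerk_speed(times, 1, T_mov) / (1.875 / T_mov)
      back <- min_jerk_speed(times - T_mov, 1, T_back) / (1.875 / T_back)
      env <- pmax(env, back)
      carrier <- cos(2 * pi * cfg$burst_exec$freq * times +
                       stats::runif(1, 0, 2 * pi))
      sig <- amp_e * env * carrier
      for (ch in exec_ch) data[tr, ch, ] <- data[tr, ch, ] + sig
    }
    # phase-lagged coupling
    for (ce in cfg$coupling_edges) {
      ph <- stats::runif(1, 0, 2 * pi)
      amp_c <- if (is.null(ce$amp)) 1 else ce$amp
      base <- 2 * pi * ce$freq * times + ph
      data[tr, ce$i, ] <- data[tr, ce$i, ] + amp_c * coup_env * cos(base)
      data[tr, ce$j, ] <- data[tr, ce$j, ] +
        amp_c * coup_env * cos(base - ce$lag)
    }
  }
  # zero-lag neighbour mixing (volume conduction)
  if (cfg$mixing_gain != 0) {
    mixed <- data
    for (ch in seq_len(n_ch)) {
      nb <- layout$neighbors[[ch]]
      if (length(nb)) {
        nb_mean <- apply(data[, nb, , drop = FALSE], c(1, 3), mean)
        mixed[, ch, ] <- data[, ch, ] + cfg$mixing_gain * nb_mean
      }
    }
    data <- mixed
  }
  structure(list(data = data, times = times, fs = fs,
                 ch_names = layout$names, trials = tab),
            class = "eeg_epochs")
}

#' @exportS3Method base::print
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples (%g Hz, %g to %g s)\n",
              d[1], d[2], d[3], x$fs, min(x$times), max(x$times)))
  invisible(x)
}

#' Generate a trial table for mixed-model recovery studies
#'
#' Simulates standardized per-trial peak velocity and movement time and an
#' extent built from fixed slopes plus per-subject random intercepts and
#' slopes, the generative structure assumed by the extent ~ PV + MT
#' mixed-effects model.
#'
#' Peak velocity and movement time are drawn with correlation `rho`
#' (default -0.5), the speed-duration trade-off of reaching: for a given
#' extent, faster movements are shorter. The negative correlation is
#' also what makes standardized slope pairs like (1.0, 0.7) attainable —
#' with orthogonal standardized predictors and a standardized outcome
#' the squared slopes could not exceed 1.
#'
#' @param n_subjects,n_trials Cohort size.
#' @param beta_pv,beta_mt Fixed standardized slopes.
#' @param rho Correlation between peak velocity and movement time.
#' @param sd_intercept,sd_slope SDs of per-subject random intercept and
#'   random slopes (applied to both predictors).
#' @param resid_sd Residual SD.
#' @param seed Integer seed.
#' @return data.frame(subject, pv, mt, extent).
#' @export
gen_lmm_cohort <- function(n_subjects = 40, n_trials = 60,
                           beta_pv = 1.0, beta_mt = 0.7, rho = -0.5,
                           sd_intercept = 0.2, sd_slope = 0.3,
                           resid_sd = 0.2, seed = 1L) {
  set.seed(as.integer(seed))
  u0 <- stats::rnorm(n_subjects, 0, sd_intercept)
  u1 <- stats::rnorm(n_subjects, 0, sd_slope)
  u2 <- stats::rnorm(n_subjects, 0, sd_slope)
  subject <- rep(seq_len(n_subjects), each = n_trials)
  pv <- stats::rnorm(n_subjects * n_trials)
  mt <- rho * pv + sqrt(1 - rho^2) * stats::rnorm(n_subjects * n_trials)
  extent <- (beta_pv + u1[subject]) * pv + (beta_mt + u2[subject]) * mt +
    u0[subject] + stats::rnorm(length(pv), 0, resid_sd)
  data.frame(subject = subject, pv = pv, mt = mt, extent = extent)
}

#' Generate per-subject summary tables for the regression screen
#'
#' Draws a cohort of subjects whose gamma burst gain is correlated (log
#' scale, correlation `r`) with their mean peak velocity, with movement
#' time negatively coupled to peak velocity, and builds noisy per-subject
#' band-power and subnetwork-wPLI summaries from the gain. This is the
#' cohort-level view of the full EEG generator, used to validate the
#' regression screen at scale.
#'
#' @param n_subjects Cohort size.
#' @param r Gain to peak-velocity coupling (log-scale correlation).
#' @param power_noise_sd Measurement noise on the (standardized)
#'   log-power summaries.
#' @param wpli_coupled If TRUE the subnetwork wPLI summary is driven by
#'   the gain like the power summaries; if FALSE it is independent noise.
#' @param seed Integer seed.
#' @return A list of aligned data.frames: `power` (subject,
#'   power_planning, power_execution), `wpli` (subject, wpli_exec),
#'   `kin` (subject, pv, mt).
#' @export
gen_subject_summaries <- function(n_subjects = 60, r = 0.6,
                                  power_noise_sd = 0.5,
                                  wpli_coupled = FALSE, seed = 1L) {
  set.seed(as.integer(seed))
  z_g <- stats::rnorm(n_subjects)
  pv <- r * z_g + sqrt(1 - r^2) * stats::rnorm(n_subjects)
  mt <- -0.6 * pv + sqrt(1 - 0.36) * stats::rnorm(n_subjects)
  noisy <- function() z_g + stats::rnorm(n_subjects, 0, power_noise_sd)
  wpli <- if (wpli_coupled) noisy() else stats::rnorm(n_subjects)
  list(power = data.frame(subject = seq_len(n_subjects),
                          power_planning = noisy(),
                          power_execution = noisy()),
       wpli = data.frame(subject = seq_len(n_subjects), wpli_exec = wpli),
       kin = data.frame(subject = seq_len(n_subjects), pv = pv, mt = mt))
}
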
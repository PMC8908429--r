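#' z-transform a vector of per-subject measures
#'
#' Mean 0, SD 1, with the sample (n - 1) denominator.
#'
#' @param values Numeric vector, length >= 2, nonzero SD.
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need >= 2 values")
  s <- stats::sd(values)
  if (is.na(s) || s == 0) stop("zero standard deviation")
  (values - mean(values)) / s
}

#' Simple linear regression of one outcome on one predictor
#'
#' Ordinary least squares with the conventional report: F against the
#' constant model, slope, SE, t, two-sided p (t distribution, n - 2 df)
#' and adjusted R-squared. With standardized y and x the slope equals
#' the Pearson correlation.
#'
#' @param y,x Numeric vectors of equal length, n >= 3; x not constant.
#' @return List of class `ols_fit`: `f_stat`, `beta`, `se`, `t`, `p`,
#'   `r2_adjusted`, `dof`, `intercept`.
#' @export
ols_fit <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  n <- length(y)
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  co <- s$coefficients
  structure(list(f_stat = unname(s$fstatistic[1]),
                 beta = co["x", "Estimate"],
                 se = co["x", "Std. Error"],
                 t = co["x", "t value"],
                 p = co["x", "Pr(>|t|)"],
                 r2_adjusted = s$adj.r.squared,
                 dof = n - 2,
                 intercept = co["(Intercept)", "Estimate"]),
            class = "ols_fit")
}

#' Regression screen of gamma measures against kinematics
#'
#' Regresses every per-subject gamma summary (band/window power means
#' and subnetwork wPLI means) on every kinematic outcome (mean peak
#' velocity, mean movement time), one simple regression per cell, after
#' z-transforming both sides. Optionally excludes subjects whose mean
#' peak velocity lies more than `exclude_sd` SD below the cohort mean
#' (low-performance exclusion) before fitting. No correction is applied
#' across the grid in the main columns; a Bonferroni-adjusted column is
#' reported alongside.
#'
#' @param power_table data.frame: `subject` plus one column per power
#'   summary.
#' @param wpli_table Optional data.frame: `subject` plus one column per
#'   subnetwork summary.
#' @param kin_table data.frame: `subject`, `pv`, `mt` (per-subject
#'   means).
#' @param exclude_sd SD multiplier for the low-performance exclusion;
#'   NULL disables it.
#' @return data.frame with one row per (measure, outcome):
#'   measure, source, outcome, n, f_stat, beta, se, t, p, r2_adjusted,
#'   p_bonferroni.
#' @export
gamma_kinematics_screen <- function(power_table, wpli_table = NULL,
                                    kin_table, exclude_sd = 2) {
  check_alignment <- function(tab, what) {
    if (is.null(tab)) return(invisible())
    if (!identical(sort(tab$subject), sort(kin_table$subject))) {
      extra <- setdiff(tab$subject, kin_table$subject)
      miss <- setdiff(kin_table$subject, tab$subject)
      stop(what, " subjects misaligned with kinematics",
           if (length(extra)) paste0("; extra: ",
                                     paste(extra, collapse = ", ")),
           if (length(miss)) paste0("; missing: ",
                                    paste(miss, collapse = ", ")))
    }
  }
  if (nrow(kin_table) < 3) stop("need >= 3 subjects")
  check_alignment(power_table, "power")
  check_alignment(wpli_table, "wPLI")

  keep <- rep(TRUE, nrow(kin_table))
  if (!is.null(exclude_sd)) {
    pv <- kin_table$pv
    keep <- pv >= mean(pv) - exclude_sd * stats::sd(pv)
  }
  kin <- kin_table[keep, ]
  sources <- list(power = power_table, wpli = wpli_table)
  rows <- list()
  for (src in names(sources)) {
    tab <- sources[[src]]
    if (is.null(tab)) next
    tab <- tab[match(kin$subject, tab$subject), ]
    for (m in setdiff(names(tab), "subject")) {
      for (outc in c("pv", "mt")) {
        fit <- ols_fit(zscore(kin[[outc]]), zscore(tab[[m]]))
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, source = src, outcome = outc, n = nrow(kin),
          f_stat = fit$f_stat, beta = fit$beta, se = fit$se, t = fit$t,
          p = fit$p, r2_adjusted = fit$r2_adjusted)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Gamma amplitude sampled at the time of peak velocity
#'
#' Alternative predictor: per trial, the band-limited power time course
#' (24 ms bins) is sampled at the bin nearest the trial's peak-velocity
#' time, then averaged over trials.
#'
#' @param tfr A normalized `eeg_tfr` with per-trial power.
#' @param band c(lo, hi) Hz.
#' @param channels Channel indices.
#' @param pv_times Per-trial peak-velocity times (s, relative to
#'   movement onset; the epoch clock).
#' @param bin_s Bin width (s).
#' @return Scalar: trial-averaged gamma amplitude at peak velocity.
#' @export
gamma_at_peak_velocity <- function(tfr, band, channels, pv_times,
                                   bin_s = 0.024) {
  fsel <- select_bins(tfr$freqs, band)
  if (!length(fsel)) stop("empty band")
  n_tr <- dim(tfr$power)[1]
  if (length(pv_times) != n_tr)
    stop("need one peak-velocity time per trial")
  vals <- vapply(seq_len(n_tr), function(tr) {
    sel <- which(abs(tfr$times - pv_times[tr]) <= bin_s / 2)
    if (!length(sel)) sel <- which.min(abs(tfr$times - pv_times[tr]))
    mean(tfr$power[tr, channels, fsel, sel])
  }, numeric(1))
  mean(vals)
}
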
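# Morlet machinery -----------------------------------------------------
#
# Complex Morlet wavelet psi(t) = A exp(-t^2 / (2 sigma^2)) exp(i 2 pi f t)
# with sigma = cycles / (2 pi f) and A = 2 / (sigma sqrt(2 pi)), so a
# unit-amplitude sinusoid at f yields |coefficient| = 1 (unit peak power).
# Any consistent normalization cancels in the baseline ratio; this one
# makes raw power interpretable in tests.
#
# Convolution is done in the frequency domain: the wavelet's transfer
# function is the (analytic) Gaussian H(f') = 2 exp(-2 pi^2 sigma^2
# (f' - f)^2), applied to the FFT of the reflection-padded signal.

morlet_sigma <- function(freqs, cycles) cycles / (2 * pi * freqs)

# per-frequency cycle counts: linear 3 -> 10 over the grid
default_cycles <- function(freqs, lo = 3, hi = 10) {
  rng <- range(freqs)
  if (diff(rng) == 0) return(rep((lo + hi) / 2, length(freqs)))
  lo + (hi - lo) * (freqs - rng[1]) / diff(rng)
}

# Reflection padding sized so the padded length is 2-3-5-smooth (fast
# FFT) while covering at least half a wavelet on each side.
choose_pad <- function(n_time, half_max_samples) {
  pad_min <- min(max(1L, half_max_samples), n_time - 1L)
  Nt <- stats::nextn(n_time + 2L * pad_min, c(2, 3, 5))
  while ((Nt - n_time) %% 2L != 0L) Nt <- stats::nextn(Nt + 1L, c(2, 3, 5))
  pad <- (Nt - n_time) %/% 2L
  if (pad > n_time - 1L) pad <- pad_min
  as.integer(pad)
}

fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

# Complex wavelet coefficients of one signal: matrix n_freqs x n_time.
morlet_coefs_1d <- function(x, fs, freqs, sigma, pad, H = NULL) {
  n <- length(x)
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[n - seq_len(pad) + 1L]))
  N <- length(xp)
  X <- stats::fft(xp)
  if (is.null(H)) H <- morlet_transfer(N, fs, freqs, sigma)
  out <- matrix(0 + 0i, length(freqs), n)
  idx <- pad + seq_len(n)
  for (fi in seq_along(freqs))
    out[fi, ] <- (stats::fft(X * H[fi, ], inverse = TRUE) / N)[idx]
  out
}

morlet_transfer <- function(N, fs, freqs, sigma) {
  fgrid <- fft_freqs(N, fs)
  H <- matrix(0, length(freqs), N)
  for (fi in seq_along(freqs))
    H[fi, ] <- 2 * exp(-2 * pi^2 * sigma[fi]^2 * (fgrid - freqs[fi])^2)
  H
}

#' Morlet wavelet time-frequency decomposition of epoched EEG
#'
#' Convolves every trial and channel with complex Morlet wavelets and
#' returns power. The number of cycles grows linearly from 3 to 10 over
#' the frequency grid (so temporal resolution is traded for frequency
#' resolution as frequency increases); the signal is reflection-padded
#' and the samples within half a wavelet length (3 sigma) of either epoch
#' edge are marked invalid per frequency rather than zero-filled.
#'
#' @param epochs An `eeg_epochs` object.
#' @param freqs Frequency grid in Hz (e.g. `seq(1, 80, 0.5)`); all below
#'   fs/2.
#' @param cycles Per-frequency cycle counts; default linear 3..10 over
#'   the grid.
#' @param keep_trials If FALSE, power is averaged over trials (the
#'   returned array keeps a singleton trial axis).
#' @param decim Keep every `decim`-th time sample of the output.
#' @return An object of class `eeg_tfr`: `power` (trials x channels x
#'   freqs x times), `freqs`, `times`, `valid` (freqs x times logical
#'   edge mask), `ch_names`, `trials`, `normalized = FALSE`.
#' @export
morlet_tfr <- function(epochs, freqs = seq(1, 80, by = 0.5),
                       cycles = NULL, keep_trials = TRUE, decim = 1L) {
  fs <- epochs$fs
  if (max(freqs) >= fs / 2) stop("max frequency must be below fs/2")
  if (is.null(cycles)) cycles <- default_cycles(freqs)
  if (length(cycles) == 1) cycles <- rep(cycles, length(freqs))
  sigma <- morlet_sigma(freqs, cycles)
  half_s <- 3 * sigma
  n_time <- dim(epochs$data)[3]
  epoch_len <- n_time / fs
  too_long <- which(2 * half_s >= epoch_len)
  if (length(too_long))
    stop(sprintf("epoch (%.2f s) shorter than the wavelet at %.1f Hz (%.2f s)",
                 epoch_len, freqs[too_long[1]], 2 * half_s[too_long[1]]))
  pad <- choose_pad(n_time, ceiling(max(half_s) * fs))

  keep_idx <- seq(1L, n_time, by = as.integer(decim))
  times_out <- epochs$times[keep_idx]
  n_tr <- dim(epochs$data)[1]; n_ch <- dim(epochs$data)[2]
  valid <- matrix(TRUE, length(freqs), length(keep_idx))
  for (fi in seq_along(freqs))
    valid[fi, ] <- times_out >= epochs$times[1] + half_s[fi] &
      times_out <= epochs$times[n_time] - half_s[fi]

  N <- n_time + 2L * pad
  H <- morlet_transfer(N, fs, freqs, sigma)
  out_tr <- if (keep_trials) n_tr else 1L
  power <- array(0, dim = c(out_tr, n_ch, length(freqs), length(keep_idx)))
  out_idx <- pad + keep_idx
  for (tr in seq_len(n_tr)) {
    xm <- epochs$data[tr, , , drop = FALSE]
    dim(xm) <- dim(xm)[2:3]
    xm <- t(xm)                                            # time x ch
    xp <- rbind(xm[rev(seq_len(pad)), , drop = FALSE], xm,
                xm[n_time - seq_len(pad) + 1L, , drop = FALSE])
    X <- stats::mvfft(xp)
    for (fi in seq_along(freqs)) {
      co <- stats::mvfft(X * H[fi, ], inverse = TRUE)[out_idx, ,
                                                      drop = FALSE] / N
      p <- t(Mod(co)^2)                                    # ch x time
      if (keep_trials) power[tr, , fi, ] <- p
      else power[1, , fi, ] <- power[1, , fi, ] + p / n_tr
    }
  }
  structure(list(power = power, freqs = freqs, times = times_out,
                 valid = valid, ch_names = epochs$ch_names,
                 trials = epochs$trials, normalized = FALSE),
            class = "eeg_tfr")
}

#' Complex Morlet coefficients for selected channels and time window
#'
#' Lower-level sibling of [morlet_tfr()] returning the complex
#' coefficients (not power) restricted to a time window, as needed for
#' cross-spectra. Uses a fixed cycle count (width).
#'
#' @param epochs An `eeg_epochs`.
#' @param freqs Hz grid.
#' @param width Cycles (constant across frequencies); the connectivity
#'   convention is width = 7.
#' @param window Time range (s) to retain.
#' @param channels Channel indices (default all).
#' @return List: `coefs` (trials x channels x freqs x window-times complex
#'   array), `freqs`, `times`, `channels`.
#' @export
morlet_coefs_window <- function(epochs, freqs, width = 7,
                                window, channels = NULL) {
  fs <- epochs$fs
  if (max(freqs) >= fs / 2) stop("max frequency must be below fs/2")
  if (is.null(channels)) channels <- seq_along(epochs$ch_names)
  sigma <- morlet_sigma(freqs, rep(width, length(freqs)))
  half_s <- 3 * sigma
  n_time <- dim(epochs$data)[3]
  t0 <- epochs$times[1]; t1 <- epochs$times[n_time]
  if (window[1] < t0 + max(half_s) || window[2] > t1 - max(half_s))
    stop("window overlaps the invalid wavelet edge region")
  sel <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (!length(sel)) stop("window contains no samples")
  pad <- choose_pad(n_time, ceiling(max(half_s) * fs))
  N <- n_time + 2L * pad
  H <- morlet_transfer(N, fs, freqs, sigma)
  n_tr <- dim(epochs$data)[1]
  coefs <- array(0 + 0i, dim = c(n_tr, length(channels), length(freqs),
                                 length(sel)))
  for (tr in seq_len(n_tr))
    for (ci in seq_along(channels)) {
      co <- morlet_coefs_1d(epochs$data[tr, channels[ci], ], fs, freqs,
                            sigma, pad, H)
      coefs[tr, ci, , ] <- co[, sel, drop = FALSE]
    }
  list(coefs = coefs, freqs = freqs, times = epochs$times[sel],
       channels = channels)
}

#' Whole-epoch baseline normalization of a TFR
#'
#' For each channel and frequency, the mean power m over all trials and
#' all valid times is the baseline; the output is (power - m) / m, a
#' baseline-relative fraction whose mean over trials and valid times is
#' zero by construction.
#'
#' @param tfr An unnormalized `eeg_tfr`.
#' @return The normalized `eeg_tfr`.
#' @export
baseline_normalize <- function(tfr) {
  if (isTRUE(tfr$normalized)) stop("TFR is already normalized")
  dm <- dim(tfr$power)
  for (ch in seq_len(dm[2]))
    for (fi in seq_len(dm[3])) {
      v <- tfr$valid[fi, ]
      if (!any(v)) next
      m <- mean(tfr$power[, ch, fi, v])
      if (m == 0) stop("degenerate (zero-power) channel ", ch,
                       " at ", tfr$freqs[fi], " Hz")
      tfr$power[, ch, fi, ] <- (tfr$power[, ch, fi, ] - m) / m
    }
  tfr$normalized <- TRUE
  tfr
}

select_bins <- function(grid, range) which(grid >= range[1] & grid <= range[2])

#' Average normalized power over a band, window and channel subset
#'
#' @param tfr A (normalized) `eeg_tfr`.
#' @param band Frequency range in Hz, c(lo, hi) inclusive.
#' @param window Time range in s, c(lo, hi) inclusive.
#' @param channels Channel indices (default all).
#' @param by_trial If TRUE return one value per trial, else the grand
#'   mean.
#' @return Numeric scalar or per-trial vector.
#' @export
band_average <- function(tfr, band, window, channels = NULL,
                         by_trial = FALSE) {
  if (is.null(channels)) channels <- seq_along(tfr$ch_names)
  fsel <- select_bins(tfr$freqs, band)
  tsel <- select_bins(tfr$times, window)
  if (!length(fsel) || !length(tsel) || !length(channels))
    stop("empty band/window/channel selection")
  ok <- tfr$valid[fsel, tsel, drop = FALSE]
  if (!any(ok)) stop("selection falls entirely in the invalid edge region")
  sub <- tfr$power[, channels, fsel, tsel, drop = FALSE]
  mask <- aperm(array(ok, dim = c(length(fsel), length(tsel),
                                  dim(sub)[1], dim(sub)[2])), c(3, 4, 1, 2))
  sub[!mask] <- NA
  if (by_trial) apply(sub, 1, mean, na.rm = TRUE)
  else mean(sub, na.rm = TRUE)
}

#' Peak frequency of window- and channel-averaged power
#'
#' Averages normalized power over trials, the time window and the channel
#' subset, then returns the frequency bin with maximum power within the
#' search band. Ties are broken toward the lower frequency and flagged.
#'
#' @inheritParams band_average
#' @param band Search band, default the gamma range c(25.5, 80).
#' @return List: `peak_hz`, `tie` (TRUE when the maximum was not
#'   unique), `spectrum` (the averaged power per frequency bin).
#' @export
peak_frequency <- function(tfr, window, band = c(25.5, 80),
                           channels = NULL) {
  if (is.null(channels)) channels <- seq_along(tfr$ch_names)
  fsel <- select_bins(tfr$freqs, band)
  tsel <- select_bins(tfr$times, window)
  if (!length(fsel) || !length(tsel) || !length(channels))
    stop("empty band/window/channel selection")
  spec <- vapply(fsel, function(fi) {
    v <- tsel[tfr$valid[fi, tsel]]
    if (!length(v)) return(NA_real_)
    mean(tfr$power[, channels, fi, v])
  }, numeric(1))
  if (all(is.na(spec))) stop("whole band falls in the invalid edge region")
  mx <- max(spec, na.rm = TRUE)
  at <- which(spec == mx)
  list(peak_hz = tfr$freqs[fsel[at[1]]], tie = length(at) > 1,
       spectrum = stats::setNames(spec, tfr$freqs[fsel]))
}

#' Band-power time course in fixed-width time bins
#'
#' Averages (normalized) power over a frequency band per channel, then
#' averages time samples into consecutive bins (24 ms by default, the
#' granularity used for the cluster statistics). Only valid (non-edge)
#' samples enter a bin; bins with no valid sample are dropped.
#'
#' @inheritParams band_average
#' @param bin_s Bin width in seconds.
#' @param window Optional time range restriction before binning.
#' @return List: `power` (channels x bins matrix, trial-averaged),
#'   `bin_centers` (s).
#' @export
band_time_course <- function(tfr, band, bin_s = 0.024, window = NULL,
                             channels = NULL) {
  if (is.null(channels)) channels <- seq_along(tfr$ch_names)
  fsel <- select_bins(tfr$freqs, band)
  if (!length(fsel)) stop("empty band selection")
  tsel <- if (is.null(window)) seq_along(tfr$times)
          else select_bins(tfr$times, window)
  tt <- tfr$times[tsel]
  valid_any <- apply(tfr$valid[fsel, tsel, drop = FALSE], 2, all)
  tsel <- tsel[valid_any]; tt <- tt[valid_any]
  if (!length(tsel)) stop("no valid samples in the requested window")
  bins <- floor((tt - tt[1]) / bin_s)
  ub <- sort(unique(bins))
  bp <- apply(tfr$power[, channels, fsel, tsel, drop = FALSE],
              c(2, 4), mean)           # channels x times
  pow <- vapply(ub, function(b) rowMeans(bp[, bins == b, drop = FALSE]),
                numeric(length(channels)))
  if (is.null(dim(pow))) pow <- matrix(pow, nrow = length(channels))
  centers <- vapply(ub, function(b) mean(tt[bins == b]), numeric(1))
  list(power = pow, bin_centers = centers)
}

#' Canonical gamma sub-bands and analysis windows
#'
#' The gamma range used throughout: broad 25.5-80 Hz, low 25.5-40,
#' medium 40.5-55, high 55.5-80; analysis windows relative to movement
#' onset: planning -152 to -52 ms, execution 52 to 500 ms, post-movement
#' 1500 to 2000 ms.
#'
#' @return Named list of c(lo, hi) ranges.
#' @export
gamma_bands <- function() {
  list(broad = c(25.5, 80), low = c(25.5, 40),
       medium = c(40.5, 55), high = c(55.5, 80))
}

#' @rdname gamma_bands
#' @export
analysis_windows <- function() {
  list(planning = c(-0.152, -0.052), execution = c(0.052, 0.500),
       post = c(1.5, 2.0))
}

#' @exportS3Method base::print
print.eeg_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<eeg_tfr>%s %d trials x %d channels x %d freqs (%g-%g Hz) x %d times\n",
              if (x$normalized) " (baseline-normalized)" else "",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs), d[4]))
  invisible(x)
}
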
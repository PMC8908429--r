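#' Trial-wise cross-spectra over a time window
#'
#' For every trial and channel pair, the cross-spectrum at each frequency
#' is the sum over the window's time bins of W_i(f, t) * conj(W_j(f, t)),
#' where W are complex Morlet coefficients with a fixed width (7 cycles
#' by default). Time points within a trial are collapsed here; across
#' trials the cross-spectra remain separate observations, which is what
#' the debiased wPLI estimator needs.
#'
#' The window must lie inside the valid (non-edge) region for every
#' requested frequency.
#'
#' @param epochs An `eeg_epochs`.
#' @param freqs Hz grid (0.5 Hz steps by convention).
#' @param width Wavelet cycles, constant over frequencies (default 7).
#' @param window Time range (s) relative to movement onset.
#' @param channels Channel indices (default all).
#' @return Object of class `cross_spectra`: `X` (trials x pairs x freqs,
#'   complex), `pairs` (2-column matrix of channel indices, upper
#'   triangle order), `freqs`, `window`, `ch_names`.
#' @export
cross_spectrum <- function(epochs, freqs, width = 7, window,
                           channels = NULL) {
  if (is.null(channels)) channels <- seq_along(epochs$ch_names)
  n_ch <- length(channels)
  if (n_ch < 2) stop("need >= 2 channels")
  fs <- epochs$fs
  sigma <- morlet_sigma(freqs, rep(width, length(freqs)))
  half_s <- 3 * sigma
  n_time <- dim(epochs$data)[3]
  if (window[1] < epochs$times[1] + max(half_s) ||
      window[2] > epochs$times[n_time] - max(half_s))
    stop("window overlaps the invalid wavelet edge region")
  sel <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (!length(sel)) stop("window contains no samples")
  pad <- choose_pad(n_time, ceiling(max(half_s) * fs))
  N <- n_time + 2L * pad
  H <- morlet_transfer(N, fs, freqs, sigma)

  pairs <- t(utils::combn(n_ch, 2))
  n_tr <- dim(epochs$data)[1]
  ut <- cbind(pairs[, 1], pairs[, 2])
  out_idx <- pad + sel
  X <- array(0 + 0i, dim = c(n_tr, nrow(pairs), length(freqs)))
  for (tr in seq_len(n_tr)) {
    xm <- epochs$data[tr, channels, , drop = FALSE]
    dim(xm) <- dim(xm)[2:3]
    xm <- t(xm)                                                # time x ch
    xp <- rbind(xm[rev(seq_len(pad)), , drop = FALSE], xm,
                xm[n_time - seq_len(pad) + 1L, , drop = FALSE])
    Xf <- stats::mvfft(xp)
    for (fi in seq_along(freqs)) {
      M <- stats::mvfft(Xf * H[fi, ], inverse = TRUE)[out_idx, ,
                                                      drop = FALSE] / N
      C <- t(M) %*% Conj(M)           # C[i, j] = sum_t M_i conj(M_j)
      X[tr, , fi] <- C[ut]
    }
  }
  structure(list(X = X, pairs = cbind(channels[pairs[, 1]],
                                      channels[pairs[, 2]]),
                 freqs = freqs, window = window,
                 ch_names = epochs$ch_names),
            class = "cross_spectra")
}

#' Debiased squared weighted phase lag index
#'
#' The weighted phase lag index measures phase synchronization from the
#' imaginary part of the cross-spectrum only, which makes it insensitive
#' to instantaneous (zero-lag, volume-conducted) coupling. The debiased
#' squared estimator is the U-statistic over distinct trial pairs
#'
#'   dwPLI^2 = ( (sum_j I_j)^2 - sum_j I_j^2 ) /
#'             ( (sum_j |I_j|)^2 - sum_j I_j^2 )
#'
#' where I_j is the imaginary cross-spectral component of trial j. It is
#' unbiased under independence, so estimates may be slightly negative;
#' they are retained unless `clip = TRUE`.
#'
#' @param cs A `cross_spectra`.
#' @param band Frequency range c(lo, hi) averaged after debiasing.
#' @param clip If TRUE negative estimates are clipped to 0.
#' @return Object of class `conn_matrix`: `W` (n_ch x n_ch symmetric,
#'   diagonal NA), `band`, `window`, `ch_names`.
#' @export
debiased_wpli <- function(cs, band = range(cs$freqs), clip = FALSE) {
  n_tr <- dim(cs$X)[1]
  if (n_tr < 2) stop("debiasing requires >= 2 trials")
  fsel <- which(cs$freqs >= band[1] & cs$freqs <= band[2])
  if (!length(fsel)) stop("band contains no frequency bins")
  n_pairs <- dim(cs$X)[2]
  vals <- numeric(n_pairs)
  for (pi in seq_len(n_pairs)) {
    I <- Im(cs$X[, pi, fsel, drop = FALSE])
    dim(I) <- c(n_tr, length(fsel))
    sI <- colSums(I)
    sI2 <- colSums(I^2)
    sAbs <- colSums(abs(I))
    num <- sI^2 - sI2
    den <- sAbs^2 - sI2
    w <- ifelse(den > 0, num / den, 0)
    vals[pi] <- mean(w)
  }
  if (clip) vals <- pmax(vals, 0)
  n_ch <- length(cs$ch_names)
  W <- matrix(NA_real_, n_ch, n_ch,
              dimnames = list(cs$ch_names, cs$ch_names))
  for (pi in seq_len(n_pairs)) {
    i <- cs$pairs[pi, 1]; j <- cs$pairs[pi, 2]
    W[i, j] <- W[j, i] <- vals[pi]
  }
  structure(list(W = W, band = band, window = cs$window,
                 ch_names = cs$ch_names),
            class = "conn_matrix")
}

#' Connectivity matrix for one window and band in one call
#'
#' Convenience wrapper: cross-spectra with [cross_spectrum()] on the
#' band's frequency bins, then [debiased_wpli()].
#'
#' @inheritParams cross_spectrum
#' @param band c(lo, hi) Hz; the wavelet grid is `seq(lo, hi, 0.5)`.
#' @return A `conn_matrix`.
#' @export
wpli_matrix <- function(epochs, band, window, width = 7,
                        channels = NULL) {
  freqs <- seq(band[1], band[2], by = 0.5)
  cs <- cross_spectrum(epochs, freqs, width = width, window = window,
                       channels = channels)
  debiased_wpli(cs, band = band)
}

#' @exportS3Method base::print
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d channels, band %g-%g Hz, window %g to %g s\n",
              nrow(x$W), x$band[1], x$band[2], x$window[1], x$window[2]))
  off <- x$W[upper.tri(x$W)]
  cat(sprintf("  dwPLI^2 range %.3f to %.3f (mean %.3f)\n",
              min(off), max(off), mean(off)))
  invisible(x)
}

#' Write / read a connectivity matrix as TSV
#'
#' Channel names as header row and first column; values tab-separated.
#'
#' @param cm A `conn_matrix` (or plain matrix with dimnames).
#' @param path File path.
#' @return `read_conn_tsv` returns the matrix.
#' @export
write_conn_tsv <- function(cm, path) {
  W <- if (inherits(cm, "conn_matrix")) cm$W else cm
  utils::write.table(W, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_conn_tsv
#' @export
read_conn_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}
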
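times_default <- seq(-1, 2.5, by = 1 / 250)

test_that("Morlet TFR localizes a pure sinusoid at its grid frequency", {
  ep <- make_signal_epochs(list(cos(2 * pi * 40 * times_default)))
  tfr <- morlet_tfr(ep, freqs = seq(1, 80, 0.5))
  spec <- vapply(seq_along(tfr$freqs), function(fi)
    mean(tfr$power[1, 1, fi, tfr$valid[fi, ]]), numeric(1))
  expect_equal(tfr$freqs[which.max(spec)], 40)
  # unit sinusoid -> unit peak power under the chosen normalization
  expect_equal(max(spec), 1, tolerance = 0.01)
  # off-peak response matches the analytic Gaussian transfer of the
  # wavelet centred at the probed frequency
  cyc <- function(f) 3 + 7 * (f - 1) / 79
  analytic <- function(f) {
    sig <- cyc(f) / (2 * pi * f)
    exp(-4 * pi^2 * sig^2 * (f - 40)^2)
  }
  expect_equal(spec[tfr$freqs == 30] / max(spec), analytic(30),
               tolerance = 0.02)
  expect_equal(spec[tfr$freqs == 50] / max(spec), analytic(50),
               tolerance = 0.02)
  # with >= 6 cycles everywhere the +-10 Hz leakage is below 10%
  tfr10 <- morlet_tfr(ep, freqs = c(30, 40, 50), cycles = 10)
  s10 <- vapply(1:3, function(fi)
    mean(tfr10$power[1, 1, fi, tfr10$valid[fi, ]]), numeric(1))
  expect_lt(s10[1] / s10[2], 0.10)
  expect_lt(s10[3] / s10[2], 0.10)
})

test_that("zero input gives zero power and edge samples are masked", {
  ep <- make_signal_epochs(list(rep(0, length(times_default))))
  tfr <- morlet_tfr(ep, freqs = c(10, 40))
  expect_equal(max(abs(tfr$power)), 0)
  # low-frequency rows must mask more edge samples than high-frequency
  expect_gt(sum(!tfr$valid[1, ]), sum(!tfr$valid[2, ]))
  expect_error(morlet_tfr(ep, freqs = c(10, 130)), "fs/2")
  short <- make_signal_epochs(list(rep(0, 100)))
  expect_error(morlet_tfr(short, freqs = c(1, 40)), "1.0 Hz")
})

test_that("white-noise power is flat over time within Monte-Carlo error", {
  set.seed(6)
  sigs <- replicate(60, stats::rnorm(length(times_default)),
                    simplify = FALSE)
  ep <- make_signal_epochs(sigs)
  tfr <- morlet_tfr(ep, freqs = 40, cycles = 7, keep_trials = FALSE)
  v <- tfr$valid[1, ]
  p <- tfr$power[1, 1, 1, v]
  t <- tfr$times[v]
  sl <- stats::coef(summary(stats::lm(p ~ t)))["t", ]
  expect_gt(sl["Pr(>|t|)"], 0.001)    # no systematic temporal trend
})

test_that("whole-epoch baseline normalization has the subtract-divide form", {
  n_t <- length(times_default)
  # constant power input -> identically zero
  ep <- make_signal_epochs(list(cos(2 * pi * 40 * times_default),
                                cos(2 * pi * 40 * times_default)))
  tfr <- morlet_tfr(ep, freqs = 40, cycles = 7)
  norm <- baseline_normalize(tfr)
  v <- norm$valid[1, ]
  expect_lt(max(abs(norm$power[, 1, 1, v])), 0.02)
  expect_error(baseline_normalize(norm), "already")

  # scale invariance: doubling input power leaves the output unchanged
  tfr2 <- tfr; tfr2$power <- tfr2$power * 2
  expect_equal(baseline_normalize(tfr2)$power, norm$power)

  # two-level toy: burst of power 2m over background m in 10% of samples
  frac <- 0.1
  n_hi <- round(frac * n_t)
  pw <- rep(1, n_t); pw[seq_len(n_hi)] <- 2
  toy <- structure(list(power = array(pw, dim = c(1, 1, 1, n_t)),
                        freqs = 40, times = times_default,
                        valid = matrix(TRUE, 1, n_t),
                        ch_names = "E001", trials = data.frame(subject = 1),
                        normalized = FALSE), class = "eeg_tfr")
  tn <- baseline_normalize(toy)
  m <- mean(pw)
  expect_equal(tn$power[1, 1, 1, 1], (2 - m) / m)
  expect_equal(tn$power[1, 1, 1, n_t], (1 - m) / m)
  expect_equal(mean(tn$power), 0, tolerance = 1e-12)

  # degenerate zero-power channel errors
  z <- make_signal_epochs(list(rep(0, n_t)))
  zt <- morlet_tfr(z, freqs = 40, cycles = 7)
  expect_error(baseline_normalize(zt), "degenerate")
})

test_that("band averages are means over the selection and linear in channels", {
  n_t <- 100
  pw <- array(0, dim = c(2, 3, 4, n_t))
  pw[1, 1, 1, ] <- 1; pw[2, 3, 4, ] <- 3
  tfr <- structure(list(power = pw, freqs = c(30, 40, 50, 60),
                        times = seq(0, 1, length.out = n_t),
                        valid = matrix(TRUE, 4, n_t),
                        ch_names = c("a", "b", "c"),
                        trials = data.frame(subject = c(1, 1)),
                        normalized = TRUE), class = "eeg_tfr")
  expect_equal(band_average(tfr, c(25, 65), c(0, 1)), mean(pw))
  # weighted mean over disjoint channel sets
  b1 <- band_average(tfr, c(25, 65), c(0, 1), channels = 1)
  b2 <- band_average(tfr, c(25, 65), c(0, 1), channels = 2:3)
  expect_equal(band_average(tfr, c(25, 65), c(0, 1)),
               (1 * b1 + 2 * b2) / 3)
  expect_error(band_average(tfr, c(90, 100), c(0, 1)), "empty")

  zero <- tfr; zero$power[] <- 0
  expect_equal(band_average(zero, c(25, 65), c(0, 1)), 0)
})

test_that("peak frequency takes the band argmax with low-frequency ties", {
  n_t <- 50
  pw <- array(0, dim = c(1, 1, 5, n_t))
  freqs <- c(30, 40, 50, 60, 70)
  pw[1, 1, 2, ] <- 1; pw[1, 1, 4, ] <- 1     # equal maxima at 40 and 60
  tfr <- structure(list(power = pw, freqs = freqs,
                        times = seq(0, 1, length.out = n_t),
                        valid = matrix(TRUE, 5, n_t),
                        ch_names = "a", trials = data.frame(subject = 1),
                        normalized = TRUE), class = "eeg_tfr")
  pk <- peak_frequency(tfr, window = c(0, 1), band = c(25, 80))
  expect_equal(pk$peak_hz, 40)
  expect_true(pk$tie)
  # invariant to positive rescaling of power
  tfr2 <- tfr; tfr2$power <- tfr2$power * 17
  expect_equal(peak_frequency(tfr2, c(0, 1), c(25, 80))$peak_hz, 40)
  # all-flat spectrum: lowest band frequency, tie flagged
  flat <- tfr; flat$power[] <- 1
  pf <- peak_frequency(flat, c(0, 1), c(25, 80))
  expect_equal(pf$peak_hz, 30)
  expect_true(pf$tie)
})

test_that("injected planning and execution bursts are recovered in band power maps", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_distance = 6, seed = 31)
  lay <- gen_layout(20, seed = 5)
  ep <- gen_eeg_epochs(gen_reach_trials(cfg), lay, cfg)
  tfr <- baseline_normalize(morlet_tfr(ep, freqs = seq(50, 70, 0.5),
                                       decim = 2))
  w <- analysis_windows()
  pk_p <- peak_frequency(tfr, w$planning, band = c(50, 70),
                         channels = region_channels(lay,
                                                    "centro-parietal"))
  pk_e <- peak_frequency(tfr, w$execution, band = c(50, 70),
                         channels = region_channels(lay,
                                                    "parieto-occipital"))
  expect_equal(pk_p$peak_hz, 54, tolerance = 0.5)
  expect_equal(pk_e$peak_hz, 66, tolerance = 0.5)
  # band-limited time course peaks inside the execution window over the
  # parieto-occipital region
  tc <- band_time_course(tfr, c(60, 70),
                         channels = region_channels(lay,
                                                    "parieto-occipital"))
  peak_bin <- which.max(colMeans(tc$power))
  expect_gt(tc$bin_centers[peak_bin], 0)
  expect_lt(tc$bin_centers[peak_bin], 0.6)
})
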
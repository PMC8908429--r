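test_that("cross-spectra carry the phase of lagged sinusoids", {
  times <- seq(-1, 2.5, by = 1 / 250)
  f0 <- 40
  # channel 2 is channel 1 delayed by a quarter cycle
  set.seed(1)
  sig <- cos(2 * pi * f0 * times)
  lagged <- cos(2 * pi * f0 * times - pi / 2)
  data <- array(0, dim = c(3, 3, length(times)))
  for (tr in 1:3) {
    data[tr, 1, ] <- sig
    data[tr, 2, ] <- lagged
    data[tr, 3, ] <- sig        # duplicate of channel 1
  }
  ep <- make_epochs(data)
  cs <- cross_spectrum(ep, freqs = c(39.5, 40, 40.5), width = 7,
                       window = c(0, 1))
  fi <- which(cs$freqs == 40)
  p12 <- which(cs$pairs[, 1] == 1 & cs$pairs[, 2] == 2)
  p13 <- which(cs$pairs[, 1] == 1 & cs$pairs[, 2] == 3)
  expect_equal(Arg(cs$X[1, p12, fi]), pi / 2, tolerance = 0.01)
  # duplicated channel: real and positive
  expect_equal(Im(cs$X[1, p13, fi]), 0, tolerance = 1e-8)
  expect_gt(Re(cs$X[1, p13, fi]), 0)
  expect_error(cross_spectrum(ep, freqs = c(40), width = 7,
                              window = c(-1, 0)), "edge")
})

test_that("independent channels have no consistent cross-spectral phase", {
  set.seed(2)
  n_tr <- 150
  times <- seq(-1, 2.5, by = 1 / 250)
  data <- array(rnorm(n_tr * 2 * length(times)),
                dim = c(n_tr, 2, length(times)))
  ep <- make_epochs(data)
  cs <- cross_spectrum(ep, freqs = 40, width = 7, window = c(0, 1))
  phases <- cs$X[, 1, 1] / Mod(cs$X[, 1, 1])
  resultant <- Mod(mean(phases))
  expect_lt(resultant, 2.5 / sqrt(n_tr))   # ~ Rayleigh null scale
})

test_that("debiased wPLI matches the brute-force trial-pair oracle", {
  set.seed(3)
  ep <- make_lagged_pair_epochs(20, noise_sd = 1)
  cs <- cross_spectrum(ep, freqs = c(39.5, 40, 40.5), width = 7,
                       window = c(0, 1))
  W <- debiased_wpli(cs, band = c(39.5, 40.5))
  oracle <- mean(vapply(1:3, function(fi)
    brute_dwpli(Im(cs$X[, 1, fi])), numeric(1)))
  expect_equal(W$W[1, 2], oracle, tolerance = 1e-10)
  expect_equal(W$W[1, 2], W$W[2, 1])
  expect_true(is.na(W$W[1, 1]))
  expect_error(debiased_wpli(cross_spectrum(
    subset_epochs(ep, 1), freqs = 40, width = 7, window = c(0, 1))),
    ">= 2 trials")
})

test_that("wPLI separates true lags from zero-lag mixing", {
  set.seed(4)
  # constant pi/2 lag: dwPLI^2 near 1
  ep <- make_lagged_pair_epochs(60, lag = pi / 2, noise_sd = 0.5)
  W1 <- wpli_matrix(ep, band = c(38, 42), window = c(0, 1))
  expect_gt(W1$W[1, 2], 0.9)

  # swapping the channels leaves the estimate unchanged
  ep_sw <- ep; ep_sw$data <- ep$data[, 2:1, , drop = FALSE]
  W1s <- wpli_matrix(ep_sw, band = c(38, 42), window = c(0, 1))
  expect_equal(W1s$W[1, 2], W1$W[1, 2], tolerance = 1e-12)

  # zero-lag mixtures of one source: near 0
  times <- seq(-1, 2.5, by = 1 / 250)
  n_tr <- 80
  data <- array(0, dim = c(n_tr, 2, length(times)))
  for (tr in seq_len(n_tr)) {
    s <- cos(2 * pi * 40 * times + runif(1, 0, 2 * pi))
    data[tr, 1, ] <- s + rnorm(length(times), 0, 0.5)
    data[tr, 2, ] <- 0.6 * s + rnorm(length(times), 0, 0.5)
  }
  W0 <- wpli_matrix(make_epochs(data), band = c(38, 42),
                    window = c(0, 1))
  expect_lt(abs(W0$W[1, 2]), 0.08)

  # clipping flag removes negative estimates
  set.seed(5)
  nn <- array(rnorm(10 * 2 * length(times)),
              dim = c(10, 2, length(times)))
  Wn <- wpli_matrix(make_epochs(nn), band = c(38, 42), window = c(0, 1))
  cs <- cross_spectrum(make_epochs(nn), freqs = seq(38, 42, 0.5),
                       width = 7, window = c(0, 1))
  Wc <- debiased_wpli(cs, band = c(38, 42), clip = TRUE)
  expect_gte(min(Wc$W[upper.tri(Wc$W)]), 0)
})

test_that("expected wPLI grows with the fraction of trials carrying the lag", {
  set.seed(6)
  times <- seq(-1, 2.5, by = 1 / 250)
  vals <- vapply(c(0.2, 0.6, 1.0), function(frac) {
    n_tr <- 60
    data <- array(rnorm(n_tr * 2 * length(times), 0, 0.8),
                  dim = c(n_tr, 2, length(times)))
    n_lag <- round(frac * n_tr)
    for (tr in seq_len(n_lag)) {
      ph <- runif(1, 0, 2 * pi)
      data[tr, 1, ] <- data[tr, 1, ] + cos(2 * pi * 40 * times + ph)
      data[tr, 2, ] <- data[tr, 2, ] +
        cos(2 * pi * 40 * times + ph - pi / 2)
    }
    wpli_matrix(make_epochs(data), band = c(38, 42),
                window = c(0, 1))$W[1, 2]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("volume-conduction mixing barely moves the estimate for lagged pairs", {
  cfg0 <- synth_config(n_subjects = 1, n_trials_per_distance = 20,
                       coupling_edges = list(list(i = 1, j = 10,
                                                  lag = pi / 2,
                                                  freq = 66, amp = 1.2)),
                       mixing_gain = 0, seed = 41)
  lay <- gen_layout(16, seed = 6)
  re <- gen_reach_trials(cfg0)
  w_at <- function(mix) {
    cfg <- cfg0; cfg$mixing_gain <- mix
    ep <- gen_eeg_epochs(re, lay, cfg)
    wpli_matrix(ep, band = c(64, 68), window = cfg$coupling_window,
                channels = c(1, 10))$W[1, 10]
  }
  expect_lt(abs(w_at(0.4) - w_at(0)), 0.05)
})
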
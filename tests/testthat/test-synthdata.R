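test_that("channel layouts satisfy the adjacency and region contract", {
  for (n in c(20, 64, 180)) {
    lay <- gen_layout(n, seed = 1)
    expect_length(lay$names, n)
    expect_setequal(unique(lay$region),
                    c("frontal", "central", "centro-parietal",
                      "parieto-occipital", "occipital", "temporal"))
    # symmetric, irreflexive, no isolated sensor
    for (i in seq_len(n)) {
      expect_false(i %in% lay$neighbors[[i]])
      expect_gte(length(lay$neighbors[[i]]), 1)
      for (j in lay$neighbors[[i]])
        expect_true(i %in% lay$neighbors[[j]])
    }
  }
  expect_error(gen_layout(8), "16")
})

test_that("different seeds give different layouts with the same invariants", {
  a <- gen_layout(32, seed = 1)
  b <- gen_layout(32, seed = 2)
  expect_false(isTRUE(all.equal(a$pos2d, b$pos2d)))
  expect_setequal(unique(b$region), unique(a$region))
})

test_that("minimum-jerk profiles follow the closed form", {
  t <- seq(0, 0.5, by = 1e-3)
  v <- min_jerk_speed(t, 10, 0.5)
  expect_equal(max(v), 1.875 * 10 / 0.5, tolerance = 1e-9)
  expect_equal(t[which.max(v)], 0.25)
  # peak velocity is linear in D at equal duration
  expect_equal(max(min_jerk_speed(t, 10, 0.5)) /
                 max(min_jerk_speed(t, 4, 0.5)), 2.5)
  expect_equal(min_jerk_pos(0.5, 10, 0.5), 10)
  expect_error(min_jerk_pos(0.1, -1, 0.5), "positive")
  expect_error(min_jerk_speed(0.1, 10, 0), "positive")
})

test_that("generated reach trials recover the configured task structure", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_distance = 20, seed = 7)
  re <- gen_reach_trials(cfg)
  expect_equal(nrow(re$trials), 2 * 3 * 20)
  expect_setequal(unique(re$trials$distance_cm), c(4, 7, 10))
  expect_setequal(unique(re$trials$direction), 1:8)
  expect_true(all(re$trials$rt_true_s >= cfg$rt_min_s))
  expect_equal(re$trials$pv_true_cm_s,
               1.875 * re$trials$distance_cm / re$trials$mt_true_s)
  # endpoint extent per distance within noise of the target distances
  kin <- kinematics_table(re, cfg)
  ext <- as.numeric(tapply(kin$extent_cm, kin$distance_cm, mean))
  expect_equal(ext, c(4, 7, 10), tolerance = 0.02)
})

test_that("generators are deterministic under a fixed config", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_distance = 2, seed = 11)
  lay <- gen_layout(20, seed = 3)
  r1 <- gen_reach_trials(cfg); r2 <- gen_reach_trials(cfg)
  expect_identical(r1, r2)
  e1 <- gen_eeg_epochs(r1, lay, cfg)
  e2 <- gen_eeg_epochs(r2, lay, cfg)
  expect_identical(e1$data, e2$data)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synth_config(distances_cm = c(7, 4, 10)), "increasing")
  expect_error(synth_config(burst_exec = list(freq = 130,
                                              window = c(0.052, 0.5),
                                              region = "parieto-occipital",
                                              gains = c(1, 1.3, 1.6),
                                              amp = 1)), "Nyquist")
  expect_error(synth_config(
    burst_plan = list(freq = 54, window = c(-0.152, -0.052),
                      region = "centro-parietal",
                      gains = c(1.6, 1.3, 1.0), amp = 0.8)),
    "nondecreasing")
  expect_error(synth_config(coupling_edges = list(
    list(i = 1, j = 2, lag = 0, freq = 40, amp = 1))), "phase lag")
})

test_that("structure-free config yields plain 1/f noise epochs", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_distance = 4,
                      burst_plan = list(freq = 54,
                                        window = c(-0.152, -0.052),
                                        region = "centro-parietal",
                                        gains = c(0, 0, 0), amp = 0),
                      burst_exec = list(freq = 66,
                                        window = c(0.052, 0.5),
                                        region = "parieto-occipital",
                                        gains = c(0, 0, 0), amp = 0),
                      seed = 5)
  lay <- gen_layout(20, seed = 3)
  ep <- gen_eeg_epochs(gen_reach_trials(cfg), lay, cfg)
  # gamma-band variance in the planning window vs a matched later window
  # should be statistically indistinguishable
  sel1 <- ep$times >= -0.5 & ep$times < 0
  sel2 <- ep$times >= 1.5 & ep$times < 2
  v1 <- apply(ep$data[, , sel1], 1:2, stats::var)
  v2 <- apply(ep$data[, , sel2], 1:2, stats::var)
  expect_equal(mean(v1) / mean(v2), 1, tolerance = 0.1)
})

test_that("per-distance burst gains order band power in the target region only", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_distance = 8, seed = 21)
  lay <- gen_layout(24, seed = 4)
  re <- gen_reach_trials(cfg)
  ep <- gen_eeg_epochs(re, lay, cfg)
  tfr <- baseline_normalize(morlet_tfr(ep, freqs = seq(55.5, 80, 0.5),
                                       decim = 2))
  w <- analysis_windows()$execution
  po <- region_channels(lay, "parieto-occipital")
  fr <- region_channels(lay, "frontal")
  by_dist <- function(ch) {
    p <- band_average(tfr, c(55.5, 80), w, ch, by_trial = TRUE)
    unname(tapply(p, tfr$trials$distance_cm, mean))
  }
  target <- by_dist(po)
  expect_true(all(diff(target) > 0))
  expect_lt(max(abs(by_dist(fr))), target[1])
})
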
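test_that("pointwise statistics handle trivial and degenerate cases", {
  set.seed(1)
  a <- array(rnorm(10 * 4 * 5), dim = c(10, 4, 5))
  res <- pointwise_stat(list(a, a), "paired_t")
  expect_equal(res$stat, matrix(0, 4, 5))
  expect_true(all(res$zero_variance))

  b <- a + 1   # constant shift: zero-variance difference, flagged not Inf
  res2 <- pointwise_stat(list(b, a), "paired_t")
  expect_true(all(is.finite(res2$stat)))
  expect_true(all(res2$zero_variance))

  # against t.test on a non-degenerate point
  b2 <- a + array(rnorm(length(a), 0.3), dim = dim(a))
  res3 <- pointwise_stat(list(b2, a), "paired_t")
  tt <- t.test(b2[, 2, 3], a[, 2, 3], paired = TRUE)$statistic
  expect_equal(res3$stat[2, 3], unname(tt), tolerance = 1e-10)
  expect_error(pointwise_stat(list(a, a, a), "paired_t"), "exactly 2")
})

test_that("repeated-measures F matches the aov oracle", {
  set.seed(2)
  n <- 9
  conds <- lapply(1:3, function(k)
    array(rnorm(n * 2 * 3, mean = 0.2 * k), dim = c(n, 2, 3)))
  res <- pointwise_stat(conds, "rm_F")
  for (ch in 1:2) for (b in 1:3) {
    vals <- sapply(conds, function(a) a[, ch, b])
    expect_equal(res$stat[ch, b], aov_rm_F(vals), tolerance = 1e-10)
  }
  expect_equal(res$df, c(2, 16))
})

test_that("cluster formation follows adjacency, gating and sign rules", {
  # 5 mutually adjacent channels, one bin, all suprathreshold
  nb5 <- lapply(1:5, function(i) setdiff(1:5, i))
  stat <- matrix(5, 5, 1)
  cl <- form_clusters(stat, threshold = 3, neighbors = nb5,
                      min_neighbors = 4)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$members), 5)
  expect_equal(cl[[1]]$mass, 25)

  # raising the neighbour requirement above what exists kills the patch
  expect_length(form_clusters(stat, 3, nb5, min_neighbors = 5), 0)

  # two patches with no connecting neighbour pair -> two clusters
  nb <- c(lapply(1:3, function(i) setdiff(1:3, i)),
          lapply(4:6, function(i) setdiff(4:6, i)))
  stat2 <- matrix(4, 6, 1)
  cl2 <- form_clusters(stat2, 3, nb, min_neighbors = 2)
  expect_length(cl2, 2)

  # no suprathreshold points -> empty
  expect_length(form_clusters(matrix(0, 6, 1), 3, nb, 0), 0)

  # negative clusters are formed separately with negative mass
  stat3 <- matrix(c(5, 5, 5, -5, -5, -5), 6, 1)
  cl3 <- form_clusters(stat3, 3, nb, min_neighbors = 2)
  expect_length(cl3, 2)
  expect_setequal(vapply(cl3, `[[`, numeric(1), "sign"), c(1, -1))

  # temporal adjacency joins same-channel suprathreshold runs
  stat4 <- matrix(0, 6, 3); stat4[1:3, 1:2] <- 5
  cl4 <- form_clusters(stat4, 3, nb, min_neighbors = 0)
  expect_length(cl4, 1)
  expect_equal(nrow(cl4[[1]]$members), 6)

  expect_error(form_clusters(matrix(0, 4, 1), 3, nb5[1:3], 0),
               "adjacency")
})

test_that("exhaustive sign-flip enumeration matches sampled permutation", {
  set.seed(3)
  nb <- lapply(1:4, function(i) setdiff(1:4, i))
  a <- array(rnorm(2 * 4 * 3, 2), dim = c(2, 4, 3))
  b <- array(rnorm(2 * 4 * 3), dim = c(2, 4, 3))
  ex <- cluster_test(list(a, b), "paired_t", alpha_point = 0.1,
                     neighbors = nb, min_neighbors = 0, n_perm = "all",
                     seed = 1)
  expect_equal(ex$n_perm, 4)          # 2^2 sign assignments
  expect_true(ex$exhaustive)
  # sampling more permutations than assignments falls back to enumeration
  sam <- cluster_test(list(a, b), "paired_t", alpha_point = 0.1,
                      neighbors = nb, min_neighbors = 0, n_perm = 1000,
                      seed = 2)
  expect_equal(vapply(ex$clusters, `[[`, numeric(1), "p"),
               vapply(sam$clusters, `[[`, numeric(1), "p"))
})

test_that("cluster p-values respect the +1/+1 convention and detect effects", {
  set.seed(4)
  lay <- gen_layout(16, seed = 9)
  n <- 12
  a <- array(rnorm(n * 16 * 8), dim = c(n, 16, 8))
  b <- array(rnorm(n * 16 * 8), dim = c(n, 16, 8))
  patch <- lay$neighbors[[1]][1:min(3, length(lay$neighbors[[1]]))]
  patch <- unique(c(1, patch))
  b[, patch, 3:5] <- b[, patch, 3:5] + 2.5
  res <- cluster_test(list(b, a), "paired_t", alpha_point = 0.01,
                      neighbors = lay$neighbors, min_neighbors = 0,
                      n_perm = 300, seed = 5)
  expect_gt(length(res$clusters), 0)
  ps <- vapply(res$clusters, `[[`, numeric(1), "p")
  expect_true(all(ps >= 1 / 301 & ps <= 1))
  expect_lt(min(ps), 0.05)
  top <- res$clusters[[1]]
  expect_true(all(top$members[, "channel"] %in% patch))
  # monotonicity on the same noise realization: bigger effect, bigger mass
  b2 <- b; b2[, patch, 3:5] <- b2[, patch, 3:5] + 1.5
  res2 <- cluster_test(list(b2, a), "paired_t", alpha_point = 0.01,
                       neighbors = lay$neighbors, min_neighbors = 0,
                       n_perm = 50, seed = 5)
  expect_gte(abs(res2$clusters[[1]]$mass), abs(top$mass))
  expect_match(res2$warnings, "n_perm", all = FALSE)
})

test_that("permutation null is exchangeable across seeds", {
  set.seed(7)
  lay <- gen_layout(16, seed = 2)
  a <- array(rnorm(10 * 16 * 6), dim = c(10, 16, 6))
  b <- array(rnorm(10 * 16 * 6), dim = c(10, 16, 6))
  r1 <- cluster_test(list(a, b), "paired_t", alpha_point = 0.05,
                     neighbors = lay$neighbors, min_neighbors = 0,
                     n_perm = 2000, seed = 11)
  r2 <- cluster_test(list(a, b), "paired_t", alpha_point = 0.05,
                     neighbors = lay$neighbors, min_neighbors = 0,
                     n_perm = 2000, seed = 99)
  ks <- suppressWarnings(stats::ks.test(r1$null_max_mass,
                                        r2$null_max_mass))
  expect_gt(ks$p.value, 0.001)
})

test_that("Friedman statistic matches the closed form and base R", {
  # identical rankings across 10 subjects, k = 3 -> chi2 = 20
  vals <- t(replicate(10, c(1, 2, 3))) + matrix(rnorm(30, 0, 1e-6), 10)
  ft <- friedman_test(vals)
  expect_equal(ft$chi2, 20, tolerance = 1e-6)
  expect_lt(ft$p, 1e-4)

  # identical conditions -> chi2 = 0, p = 1
  same <- matrix(rep(rnorm(6), 3), 6, 3)
  f0 <- friedman_test(same)
  expect_equal(f0$chi2, 0)
  expect_equal(f0$p, 1)

  # agreement with stats::friedman.test, including ties
  set.seed(8)
  y <- matrix(sample(1:4, 12 * 4, replace = TRUE), 12, 4)
  mine <- friedman_test(y)
  base <- stats::friedman.test(y)
  expect_equal(mine$chi2, unname(base$statistic), tolerance = 1e-10)
  expect_equal(mine$p, base$p.value, tolerance = 1e-10)

  # null calibration of the rejection rate
  # large enough n for the chi-square approximation to be accurate
  n_sims <- 1000
  rej <- vapply(seq_len(n_sims), function(i) {
    set.seed(1000 + i)
    friedman_test(matrix(rnorm(75), 25, 3))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 1.96 * sqrt(0.05 * 0.95 / n_sims) + 0.005)
})

test_that("Dunn post-hoc tests separate the deviant condition and cap p", {
  same <- matrix(rep(rnorm(8), 3), 8, 3)
  d0 <- dunn_posthoc(same)
  expect_true(all(d0$p_adjusted == 1))

  set.seed(9)
  y <- cbind(rnorm(15), rnorm(15), rnorm(15) + 3)  # 3 x noise SD apart
  d1 <- dunn_posthoc(y)
  sep <- d1$cond_a == "cond3" | d1$cond_b == "cond3"
  expect_true(all(d1$p_adjusted[sep] < 0.05))
  expect_gt(d1$p_adjusted[!sep], 0.05)
  expect_true(all(d1$p_adjusted == pmin(1, d1$p_raw * 3)))
})
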
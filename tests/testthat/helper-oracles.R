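# Independent oracles and small fixture builders used across the suite.

# Wrap a plain trials x channels x time array as an eeg_epochs object.
make_epochs <- function(data, fs = 250, t0 = -1) {
  d <- dim(data)
  structure(list(data = data,
                 times = t0 + (seq_len(d[3]) - 1) / fs,
                 fs = fs,
                 ch_names = sprintf("E%03d", seq_len(d[2])),
                 trials = data.frame(subject = rep(1L, d[1]))),
            class = "eeg_epochs")
}

# Single-channel epochs carrying one signal per trial (list of vectors).
make_signal_epochs <- function(signals, fs = 250, t0 = -1) {
  n <- length(signals[[1]])
  data <- array(0, dim = c(length(signals), 1, n))
  for (i in seq_along(signals)) data[i, 1, ] <- signals[[i]]
  make_epochs(data, fs = fs, t0 = t0)
}

# Two-channel narrow-band trials with a fixed phase lag and additive noise.
make_lagged_pair_epochs <- function(n_trials, freq = 40, lag = pi / 2,
                                    noise_sd = 0.5, fs = 250,
                                    times = seq(-1, 2.5, by = 1 / 250),
                                    amp2 = 1) {
  data <- array(0, dim = c(n_trials, 2, length(times)))
  for (tr in seq_len(n_trials)) {
    ph <- stats::runif(1, 0, 2 * pi)
    data[tr, 1, ] <- cos(2 * pi * freq * times + ph) +
      stats::rnorm(length(times), 0, noise_sd)
    data[tr, 2, ] <- amp2 * cos(2 * pi * freq * times + ph - lag) +
      stats::rnorm(length(times), 0, noise_sd)
  }
  make_epochs(data, fs = fs, t0 = times[1])
}

# Brute-force debiased squared wPLI: double loop over distinct trial pairs
# of the imaginary cross-spectral components (one frequency).
brute_dwpli <- function(I) {
  n <- length(I)
  num <- 0; den <- 0
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    num <- num + I[j] * I[k]
    den <- den + abs(I[j]) * abs(I[k])
  }
  if (den == 0) 0 else num / den
}

# Union-find connected components over an edge list (2-column matrix).
uf_components <- function(edges, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

# Max suprathreshold component edge count via union-find (oracle for NBS).
uf_max_component_edges <- function(supra, pairs, n_nodes) {
  if (!any(supra)) return(0L)
  ep <- pairs[supra, , drop = FALSE]
  memb <- uf_components(ep, n_nodes)
  edge_comp <- memb[ep[, 1]]
  max(table(edge_comp))
}

# Two-stage per-subject OLS estimate of the fixed slopes (oracle for the
# mixed model): fit extent ~ pv + mt per subject on globally z-scored
# data, then average the per-subject coefficients.
two_stage_ols <- function(extent, pv, mt, subject) {
  z <- function(v) (v - mean(v)) / stats::sd(v)
  d <- data.frame(extent = z(extent), pv = z(pv), mt = z(mt),
                  subject = subject)
  co <- t(vapply(split(d, d$subject), function(dd)
    stats::coef(stats::lm(extent ~ pv + mt, dd))[c("pv", "mt")],
    numeric(2)))
  colMeans(co)
}

# One-way repeated-measures F via aov (oracle for rm_F_points).
aov_rm_F <- function(values) {   # subjects x conditions
  n <- nrow(values); k <- ncol(values)
  d <- data.frame(y = as.vector(values),
                  subject = factor(rep(seq_len(n), k)),
                  cond = factor(rep(seq_len(k), each = n)))
  fit <- summary(stats::aov(y ~ cond + Error(subject), data = d))
  fit[["Error: Within"]][[1]]["cond", "F value"]
}
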
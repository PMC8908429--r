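# Pointwise statistics --------------------------------------------------

#' Pointwise paired-t or repeated-measures F maps
#'
#' Computes, for every (channel, bin) point, a paired t statistic across
#' subjects (exactly two conditions) or a one-way repeated-measures F
#' (two or more conditions, condition within subject). Points with zero
#' variance get statistic 0 and are flagged rather than returning
#' infinities.
#'
#' @param data List of condition arrays, each subjects x channels x bins
#'   (or subjects x points matrices).
#' @param kind `"paired_t"` or `"rm_F"`.
#' @return List: `stat` (channels x bins matrix, or vector for matrix
#'   input), `zero_variance` (logical map), `kind`, `df` (degrees of
#'   freedom: n-1 for t, c(k-1, (n-1)(k-1)) for F).
#' @export
pointwise_stat <- function(data, kind = c("paired_t", "rm_F")) {
  kind <- match.arg(kind)
  shaped <- lapply(data, as_points)
  dims <- attr(shaped[[1]], "map_dim")
  n <- nrow(shaped[[1]])
  if (n < 2) stop("need >= 2 subjects")
  if (kind == "paired_t") {
    if (length(shaped) != 2) stop("paired_t requires exactly 2 conditions")
    D <- shaped[[1]] - shaped[[2]]
    res <- paired_t_points(D)
    df <- n - 1
  } else {
    if (length(shaped) < 2) stop("rm_F requires >= 2 conditions")
    arr <- simplify2array(shaped)           # subj x points x cond
    arr <- aperm(arr, c(1, 3, 2))           # subj x cond x points
    res <- rm_F_points(arr)
    k <- length(shaped)
    df <- c(k - 1, (n - 1) * (k - 1))
  }
  list(stat = reshape_map(res$stat, dims),
       zero_variance = reshape_map(res$zero, dims),
       kind = kind, df = df)
}

as_points <- function(x) {
  if (length(dim(x)) == 3) {
    d <- dim(x)
    out <- matrix(x, nrow = d[1])
    attr(out, "map_dim") <- d[2:3]
    out
  } else {
    out <- as.matrix(x)
    attr(out, "map_dim") <- NULL
    out
  }
}

reshape_map <- function(v, dims) {
  if (is.null(dims)) v else matrix(v, dims[1], dims[2])
}

# t over subjects of a difference matrix (subjects x points)
paired_t_points <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  zero <- v <= .Machine$double.eps * pmax(colSums(D^2), 1)
  t <- ifelse(zero, 0, m / sqrt(pmax(v, .Machine$double.eps) / n))
  list(stat = t, zero = zero)
}

# one-way repeated-measures F per point; arr is subj x cond x points
rm_F_points <- function(arr) {
  n <- dim(arr)[1]; k <- dim(arr)[2]; p <- dim(arr)[3]
  flat <- matrix(arr, nrow = n * k)            # (subj,cond) x points
  gm <- colMeans(flat)
  ss_tot <- colSums(flat^2) - n * k * gm^2
  cond_means <- apply(arr, c(2, 3), mean)      # cond x points
  ss_cond <- n * (colSums(cond_means^2) - k * gm^2)
  subj_means <- apply(arr, c(1, 3), mean)      # subj x points
  ss_subj <- k * (colSums(subj_means^2) - n * gm^2)
  ss_err <- pmax(ss_tot - ss_cond - ss_subj, 0)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  ms_err <- ss_err / df2
  zero <- ms_err <= .Machine$double.eps * pmax(ss_tot, 1)
  f <- ifelse(zero, 0, (ss_cond / df1) / pmax(ms_err, .Machine$double.eps))
  list(stat = f, zero = zero)
}

# Cluster formation -----------------------------------------------------

#' Form supra-threshold clusters over channels x bins
#'
#' Points whose statistic exceeds `threshold` are supra-threshold. A
#' supra-threshold point is cluster-eligible only if at least
#' `min_neighbors` of its spatial neighbours are also supra-threshold at
#' the same bin (with the same sign, for signed statistics). Eligible
#' points are grouped into connected components over spatial-neighbour
#' links within a bin and same-channel links between adjacent bins.
#' For signed statistics, positive and negative clusters are formed
#' separately.
#'
#' @param stat Channels x bins statistic matrix (a vector is treated as
#'   one bin).
#' @param threshold Positive statistic cutoff (|stat| > threshold for
#'   signed maps).
#' @param neighbors List of spatial neighbour index vectors (one per
#'   channel), e.g. `layout$neighbors`.
#' @param min_neighbors Minimum supra-threshold spatial neighbours
#'   required for eligibility (0 disables the gate).
#' @param signed If TRUE (t-like maps), negative clusters are formed from
#'   stat < -threshold.
#' @return List of clusters, each with `members` (two-column matrix of
#'   channel and bin indices), `mass` (sum of the statistic), `sign`;
#'   sorted by decreasing |mass|.
#' @export
form_clusters <- function(stat, threshold, neighbors, min_neighbors = 0,
                          signed = TRUE) {
  if (is.null(dim(stat))) stat <- matrix(stat, ncol = 1)
  if (length(neighbors) != nrow(stat))
    stop("adjacency must cover all channels")
  out <- cluster_one_sign(stat, threshold, neighbors, min_neighbors, +1)
  if (signed)
    out <- c(out, cluster_one_sign(-stat, threshold, neighbors,
                                   min_neighbors, -1))
  out[order(-vapply(out, function(cl) abs(cl$mass), numeric(1)))]
}

cluster_one_sign <- function(stat, threshold, neighbors, min_neighbors,
                             sign) {
  supra <- stat > threshold
  if (!any(supra)) return(list())
  n_ch <- nrow(stat); n_b <- ncol(stat)
  eligible <- supra
  if (min_neighbors > 0) {
    for (b in seq_len(n_b)) {
      sb <- supra[, b]
      if (!any(sb)) next
      for (ch in which(sb)) {
        if (sum(sb[neighbors[[ch]]]) < min_neighbors)
          eligible[ch, b] <- FALSE
      }
    }
  }
  if (!any(eligible)) return(list())
  comp <- matrix(0L, n_ch, n_b)
  next_id <- 0L
  clusters <- list()
  for (start in which(eligible)) {
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    queue <- start
    members <- integer(0)
    comp[start] <- next_id
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- c(members, p)
      ch <- ((p - 1L) %% n_ch) + 1L
      b <- ((p - 1L) %/% n_ch) + 1L
      cand <- c((b - 1L) * n_ch + neighbors[[ch]],
                if (b > 1L) p - n_ch,
                if (b < n_b) p + n_ch)
      cand <- cand[eligible[cand] & comp[cand] == 0L]
      comp[cand] <- next_id
      queue <- c(queue, cand)
    }
    ch_i <- ((members - 1L) %% n_ch) + 1L
    b_i <- ((members - 1L) %/% n_ch) + 1L
    clusters[[next_id]] <- list(
      members = cbind(channel = ch_i, bin = b_i),
      mass = sign * sum(stat[members]), sign = sign)
  }
  clusters
}

max_cluster_mass <- function(stat, threshold, neighbors, min_neighbors,
                             signed) {
  cl <- form_clusters(stat, threshold, neighbors, min_neighbors, signed)
  if (!length(cl)) 0 else max(vapply(cl, function(x) abs(x$mass),
                                     numeric(1)))
}

# Permutation machinery -------------------------------------------------

# Sign-flip matrix for the paired-t null: n_perm x n_subjects of +-1.
# n_perm = "all" enumerates all 2^n assignments (identity included).
sign_flips <- function(n_subjects, n_perm) {
  if (identical(n_perm, "all") ||
      (is.numeric(n_perm) && n_perm >= 2^n_subjects)) {
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n_subjects)))
    dimnames(flips) <- NULL
    attr(flips, "exhaustive") <- TRUE
    return(flips)
  }
  flips <- matrix(sample(c(1, -1), n_perm * n_subjects, replace = TRUE),
                  nrow = n_perm)
  attr(flips, "exhaustive") <- FALSE
  flips
}

# t maps for every sign flip at once: flips (P x n), D (n x points).
# Sign flips leave each point's sum of squares unchanged, so only the
# mean varies across permutations.
flip_t_maps <- function(D, flips) {
  n <- nrow(D)
  M <- flips %*% D / n
  ss <- colSums(D^2)
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  V[V < 0] <- 0
  zero <- ss <= .Machine$double.eps
  Tm <- M / sqrt(pmax(V, .Machine$double.eps) / n)
  Tm[, zero] <- 0
  Tm[V <= matrix(.Machine$double.eps * pmax(ss, 1), nrow(Tm), ncol(Tm),
                 byrow = TRUE)] <- 0
  Tm
}

#' Cluster-based permutation test over channels x bins
#'
#' Nonparametric family-wise-error control for spatio-temporal maps:
#' pointwise statistics are thresholded at the parametric critical value
#' for `alpha_point` (two-sided for t), supra-threshold points are
#' grouped into clusters under the sensor adjacency with the
#' `min_neighbors` gate, and each observed cluster's mass (sum of the
#' statistic) is compared with the permutation distribution of the
#' maximum cluster mass. Permutation schemes: random within-subject sign
#' flips of the condition difference (paired t) or within-subject
#' permutation of condition labels (repeated-measures F). The p-value
#' convention includes the observed statistic in the null (the +1/+1
#' form), so p is never 0; with `n_perm = "all"` (paired t only) the
#' sign-flip null is enumerated exhaustively.
#'
#' @inheritParams pointwise_stat
#' @param alpha_point Pointwise gating alpha (parametric, two-sided for
#'   t). Default 0.001.
#' @param neighbors Spatial adjacency list (e.g. `layout$neighbors`).
#' @param min_neighbors Minimum supra-threshold spatial neighbours for
#'   cluster eligibility. Default 4.
#' @param n_perm Number of permutations, or `"all"`.
#' @param alpha_cluster Cluster-level alpha reported in the summary.
#' @param seed Integer seed.
#' @return An object of class `cluster_result`: `clusters` (each with
#'   members, mass, sign, `p` and Monte-Carlo `ci`), `null_max_mass`,
#'   `threshold`, `stat`, `kind`, `n_perm`, `seed`, `warnings`.
#' @export
cluster_test <- function(data, kind = c("paired_t", "rm_F"),
                         alpha_point = 0.001, neighbors,
                         min_neighbors = 4, n_perm = 1000,
                         alpha_cluster = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  warnings <- character(0)
  if (is.numeric(n_perm) && n_perm < 100)
    warnings <- c(warnings, "n_perm < 100: p-values are very coarse")

  obs <- pointwise_stat(data, kind)
  n <- nrow(as_points(data[[1]]))
  signed <- kind == "paired_t"
  threshold <- if (signed) stats::qt(1 - alpha_point / 2, df = n - 1)
               else stats::qf(1 - alpha_point, obs$df[1], obs$df[2])
  clusters <- form_clusters(obs$stat, threshold, neighbors, min_neighbors,
                            signed)

  shaped <- lapply(data, as_points)
  dims <- attr(shaped[[1]], "map_dim")
  if (kind == "paired_t") {
    D <- shaped[[1]] - shaped[[2]]
    flips <- sign_flips(n, n_perm)
    Tm <- flip_t_maps(D, flips)
    null_max <- apply_max_mass(Tm, dims, threshold, neighbors,
                               min_neighbors, signed)
    n_eff <- nrow(flips)
    exhaustive <- isTRUE(attr(flips, "exhaustive"))
  } else {
    k <- length(shaped)
    arr <- aperm(simplify2array(shaped), c(1, 3, 2))   # subj x cond x pts
    null_max <- numeric(n_perm)
    for (pi in seq_len(n_perm)) {
      parr <- arr
      for (s in seq_len(n)) parr[s, , ] <- arr[s, sample(k), ]
      f <- rm_F_points(parr)$stat
      null_max[pi] <- max_cluster_mass(reshape_map(f, dims), threshold,
                                       neighbors, min_neighbors, FALSE)
    }
    n_eff <- n_perm
    exhaustive <- FALSE
  }

  for (i in seq_along(clusters)) {
    obs_mass <- abs(clusters[[i]]$mass)
    if (exhaustive) {
      p <- mean(null_max >= obs_mass - 1e-12)
    } else {
      p <- (1 + sum(null_max >= obs_mass - 1e-12)) / (1 + n_eff)
    }
    half <- 1.96 * sqrt(p * (1 - p) / n_eff)
    clusters[[i]]$p <- p
    clusters[[i]]$ci <- c(max(0, p - half), min(1, p + half))
  }
  structure(list(clusters = clusters, null_max_mass = null_max,
                 threshold = threshold, stat = obs$stat, kind = kind,
                 alpha_point = alpha_point, alpha_cluster = alpha_cluster,
                 min_neighbors = min_neighbors, n_perm = n_eff,
                 exhaustive = exhaustive, seed = as.integer(seed),
                 warnings = warnings),
            class = "cluster_result")
}

apply_max_mass <- function(Tm, dims, threshold, neighbors, min_neighbors,
                           signed) {
  apply(Tm, 1, function(row) {
    if (all(abs(row) <= threshold)) return(0)
    max_cluster_mass(reshape_map(row, dims), threshold, neighbors,
                     min_neighbors, signed)
  })
}

#' @exportS3Method base::print
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, %d permutations%s, threshold %.3f\n",
              x$kind, x$n_perm,
              if (x$exhaustive) " (exhaustive)" else "", x$threshold))
  if (!length(x$clusters)) { cat("  no clusters\n"); return(invisible(x)) }
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: %d points, mass %.1f, p = %.4f [%.4f, %.4f]\n",
                i, nrow(cl$members), cl$mass, cl$p, cl$ci[1], cl$ci[2]))
  }
  invisible(x)
}

# Friedman / Dunn -------------------------------------------------------

#' Friedman rank test for related samples
#'
#' Within-subject mid-ranks, chi-square statistic with the standard tie
#' correction, p from chi-square with k - 1 degrees of freedom. When all
#' subjects have constant rows the statistic is 0 with p = 1.
#'
#' @param values Subjects x conditions matrix, no missing cells.
#' @return List: `chi2`, `dof`, `p`, `mean_ranks`.
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions")
  if (anyNA(values)) stop("missing cells are not allowed")
  r <- t(apply(values, 1, rank))
  Rj <- colSums(r)
  chi_raw <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(values, 1, function(row) {
    t_g <- table(row)
    sum(t_g^3 - t_g)
  }))
  C <- 1 - ties / (n * (k^3 - k))
  if (C <= 0) return(list(chi2 = 0, dof = k - 1, p = 1,
                          mean_ranks = Rj / n))
  chi2 <- chi_raw / C
  list(chi2 = chi2, dof = k - 1,
       p = stats::pchisq(chi2, k - 1, lower.tail = FALSE),
       mean_ranks = Rj / n)
}

#' Dunn's post-hoc test after Friedman, Bonferroni-corrected
#'
#' Pairwise z statistics from mean-rank differences with standard error
#' sqrt(k (k + 1) / (6 n)); two-sided p multiplied by the number of
#' pairs and capped at 1.
#'
#' @param values Subjects x conditions matrix.
#' @param correction Only `"bonferroni"`.
#' @return data.frame: cond_a, cond_b, z, p_raw, p_adjusted.
#' @export
dunn_posthoc <- function(values, correction = "bonferroni") {
  correction <- match.arg(correction)
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  ft <- friedman_test(values)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  labels <- colnames(values)
  if (is.null(labels)) labels <- paste0("cond", seq_len(k))
  out <- data.frame(cond_a = labels[pairs[1, ]],
                    cond_b = labels[pairs[2, ]],
                    z = (ft$mean_ranks[pairs[1, ]] -
                           ft$mean_ranks[pairs[2, ]]) / se)
  out$p_raw <- 2 * stats::pnorm(-abs(out$z))
  out$p_adjusted <- pmin(1, out$p_raw * n_pairs)
  out
}
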
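# Network Based Statistics ----------------------------------------------

#' Upper-triangle edge index of an n-node network
#'
#' @param n_nodes Number of nodes.
#' @return Two-column matrix (node_a, node_b), column-major upper
#'   triangle order — the order used by `conn_stack` and `nbs_test`.
#' @export
upper_pairs <- function(n_nodes) {
  idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  colnames(idx) <- c("node_a", "node_b")
  idx
}

#' Stack per-subject connectivity matrices into a subjects x edges matrix
#'
#' @param matrices List of `conn_matrix` objects (or plain symmetric
#'   matrices), one per subject.
#' @return List: `edges` (subjects x edges matrix of upper-triangle
#'   values), `pairs` (edge index from [upper_pairs()]), `n_nodes`.
#' @export
conn_stack <- function(matrices) {
  ws <- lapply(matrices, function(m) if (inherits(m, "conn_matrix")) m$W
                                     else as.matrix(m))
  n <- nrow(ws[[1]])
  ut <- upper.tri(ws[[1]])
  ord <- order(which(ut))      # column-major, matches upper_pairs
  edges <- t(vapply(ws, function(W) W[ut][ord], numeric(sum(ut))))
  list(edges = edges, pairs = upper_pairs(n), n_nodes = n)
}

#' Edge-wise statistics across subjects
#'
#' Mass-univariate paired t or repeated-measures F per edge, same
#' definitions as [pointwise_stat()] (it is the same code path).
#'
#' @param stacks List of condition-wise subjects x edges matrices
#'   (matched subjects).
#' @param kind `"paired_t"` or `"rm_F"`.
#' @return List: `stat` (per-edge vector), `zero_variance`, `kind`,
#'   `df`.
#' @export
edge_stats <- function(stacks, kind = c("paired_t", "rm_F")) {
  pointwise_stat(stacks, match.arg(kind))
}

# Maximal suprathreshold component size (edge count or stat sum) given
# per-edge logical `supra` and weights; fast paths avoid graph
# construction for the sparse permutation maps.
max_component_size <- function(supra, pairs, weights, mode) {
  k <- sum(supra)
  if (k == 0) return(0)
  ep <- pairs[supra, , drop = FALSE]
  w <- weights[supra]
  if (k == 1) return(if (mode == "extent") 1 else w)
  nodes <- c(ep[, 1], ep[, 2])
  if (!anyDuplicated(nodes))
    return(if (mode == "extent") 1 else max(w))
  g <- igraph::graph_from_edgelist(matrix(as.character(ep), ncol = 2),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  ma <- comp[as.character(ep[, 1])]
  size <- tapply(if (mode == "extent") rep(1, k) else w, ma, sum)
  max(size)
}

#' Network Based Statistics permutation test
#'
#' Edge-wise statistics are thresholded at `threshold`; suprathreshold
#' edges form a graph whose connected components are the candidate
#' subnetworks. The permutation null of the maximal component size
#' (edge count in `"extent"` mode, summed statistic in `"intensity"`
#' mode) gives each component a family-wise-error-corrected p-value,
#' p = (1 + #(null >= observed)) / (1 + n_perm). Permutation schemes:
#' within-subject sign flips (paired t) or within-subject condition
#' label permutation (repeated-measures F). For the paired t the
#' `alternative` selects the tail the threshold applies to; with
#' `"two.sided"` positive and negative components are formed separately.
#'
#' @inheritParams edge_stats
#' @param threshold Primary statistic cutoff (> 0), e.g. the t-score
#'   4.8 used for paired contrasts at full cohort size.
#' @param n_perm Number of permutations.
#' @param alpha Component-level alpha for the `significant` flag.
#' @param seed Integer seed.
#' @param mode Component size: `"extent"` (edge count) or
#'   `"intensity"` (summed statistic).
#' @param alternative For paired t: `"greater"` (stat > threshold) or
#'   `"two.sided"` (|stat| > threshold).
#' @return Object of class `nbs_result`: `components` (each with
#'   `edges` — row indices into `pairs` —, `pairs`, `nodes`, `n_edges`,
#'   `n_nodes`, `size`, `p`, `significant`), `edge_stats`, `threshold`,
#'   `null_max_size`, `n_perm`, `mode`, `seed`.
#' @export
nbs_test <- function(stacks, kind = c("paired_t", "rm_F"),
                     threshold = 4.8,
                     n_perm = 1000, alpha = 0.05, seed = 1L,
                     mode = c("extent", "intensity"),
                     alternative = c("greater", "two.sided")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (threshold <= 0) stop("threshold must be > 0")
  set.seed(as.integer(seed))

  stacks <- lapply(stacks, as.matrix)
  n <- nrow(stacks[[1]])
  n_edges <- ncol(stacks[[1]])
  n_nodes <- (1 + sqrt(1 + 8 * n_edges)) / 2
  if (n_nodes != round(n_nodes))
    stop("edge count is not an upper triangle of any node count")
  pairs <- upper_pairs(n_nodes)

  es <- edge_stats(stacks, kind)
  obs_stat <- as.numeric(es$stat)
  signed <- kind == "paired_t" && alternative == "two.sided"

  observed_components <- function(stat) {
    comps <- list()
    tails <- if (signed) c(1, -1) else 1
    for (sgn in tails) {
      s <- sgn * stat
      supra <- s > threshold
      if (!any(supra)) next
      ep <- pairs[supra, , drop = FALSE]
      eidx <- which(supra)
      g <- igraph::graph_from_edgelist(matrix(as.character(ep), ncol = 2),
                                       directed = FALSE)
      memb <- igraph::components(g)$membership
      ma <- memb[as.character(ep[, 1])]
      for (cid in unique(ma)) {
        rows <- eidx[ma == cid]
        comps[[length(comps) + 1L]] <- list(
          edges = rows,
          pairs = pairs[rows, , drop = FALSE],
          nodes = sort(unique(c(pairs[rows, ]))),
          n_edges = length(rows),
          n_nodes = length(unique(c(pairs[rows, ]))),
          size = if (mode == "extent") length(rows)
                 else sum(abs(stat[rows])),
          sign = sgn)
      }
    }
    comps
  }
  comps <- observed_components(obs_stat)

  perm_max <- function(stat) {
    if (signed) {
      m1 <- max_component_size(stat > threshold, pairs, abs(stat), mode)
      m2 <- max_component_size(-stat > threshold, pairs, abs(stat), mode)
      max(m1, m2)
    } else {
      max_component_size(stat > threshold, pairs, abs(stat), mode)
    }
  }

  if (kind == "paired_t") {
    D <- stacks[[1]] - stacks[[2]]
    flips <- sign_flips(n, n_perm)
    Tm <- flip_t_maps(D, flips)
    null_max <- apply(Tm, 1, perm_max)
    n_eff <- nrow(flips)
  } else {
    k <- length(stacks)
    arr <- aperm(simplify2array(stacks), c(1, 3, 2))
    null_max <- numeric(n_perm)
    for (pi in seq_len(n_perm)) {
      parr <- arr
      for (s in seq_len(n)) parr[s, , ] <- arr[s, sample(k), ]
      null_max[pi] <- perm_max(rm_F_points(parr)$stat)
    }
    n_eff <- n_perm
  }

  for (i in seq_along(comps)) {
    p <- (1 + sum(null_max >= comps[[i]]$size - 1e-12)) / (1 + n_eff)
    comps[[i]]$p <- p
    comps[[i]]$significant <- p < alpha
  }
  comps <- comps[order(-vapply(comps, `[[`, numeric(1), "size"))]
  structure(list(components = comps, edge_stats = obs_stat,
                 threshold = threshold, null_max_size = null_max,
                 n_perm = n_eff, alpha = alpha, mode = mode, kind = kind,
                 alternative = alternative, seed = as.integer(seed)),
            class = "nbs_result")
}

#' Mean connectivity over a subnetwork's edges
#'
#' Arithmetic mean of the matrix values on the component's edges — the
#' per-subject summary used as a regression predictor.
#'
#' @param matrix A `conn_matrix` or plain symmetric matrix.
#' @param component Two-column matrix of node index pairs (e.g. a
#'   component's `pairs`).
#' @return Scalar mean weight.
#' @export
subnetwork_mean <- function(matrix, component) {
  W <- if (inherits(matrix, "conn_matrix")) matrix$W else as.matrix(matrix)
  component <- as.matrix(component)
  if (!nrow(component)) stop("component has no edges")
  if (max(component) > nrow(W) || min(component) < 1)
    stop("component refers to nodes outside the matrix")
  vals <- W[cbind(component[, 1], component[, 2])]
  if (anyNA(vals)) stop("component includes edges missing from the matrix")
  mean(vals)
}

#' @exportS3Method base::print
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %s, threshold %.2f, %d permutations, %s mode\n",
              x$kind, x$threshold, x$n_perm, x$mode))
  if (!length(x$components)) { cat("  no components\n"); return(invisible(x)) }
  for (i in seq_along(x$components)) {
    cm <- x$components[[i]]
    cat(sprintf("  component %d: %d edges / %d nodes, size %.1f, p = %.4f%s\n",
                i, cm$n_edges, cm$n_nodes, cm$size, cm$p,
                if (cm$significant) " *" else ""))
  }
  invisible(x)
}

#' Export an NBS component as an edge-list TSV
#'
#' Columns node_a, node_b (names when available) and the edge statistic.
#'
#' @param result An `nbs_result`.
#' @param component Component index.
#' @param path Output file.
#' @param ch_names Optional channel names.
#' @export
write_nbs_edges_tsv <- function(result, component, path,
                                ch_names = NULL) {
  cm <- result$components[[component]]
  a <- cm$pairs[, 1]; b <- cm$pairs[, 2]
  if (!is.null(ch_names)) { a <- ch_names[a]; b <- ch_names[b] }
  utils::write.table(
    data.frame(node_a = a, node_b = b,
               stat = result$edge_stats[cm$edges]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
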
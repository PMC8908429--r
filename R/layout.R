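#' Generate a quasi-uniform scalp channel layout
#'
#' Places `n_channels` sensors quasi-uniformly on a unit disc (a 2-D
#' projection of the scalp, nose up), assigns each to a scalp region, and
#' derives a sensor adjacency (neighbourhood) structure from inter-sensor
#' distance. The adjacency is what cluster-based permutation statistics use
#' to decide which sensors count as spatial neighbours.
#'
#' Sensors are laid out on a sunflower (Fibonacci) spiral with a small
#' seeded jitter, so two seeds give different — but equally valid —
#' layouts. Regions are assigned from the anterior-posterior (y) position,
#' with lateral sensors in the mid band labelled temporal:
#' frontal, central, centro-parietal, parieto-occipital, occipital,
#' temporal.
#'
#' Neighbours are sensor pairs closer than `neighbor_factor` times the
#' median nearest-neighbour distance; every sensor is additionally linked
#' to its single nearest neighbour so no sensor is isolated. The relation
#' is symmetric and irreflexive.
#'
#' @param n_channels Number of sensors (>= 16 so that every region is
#'   populated).
#' @param seed Integer seed for the jitter.
#' @param neighbor_factor Multiplier on the median nearest-neighbour
#'   distance used as the adjacency radius. Default 1.6.
#' @return An object of class `reach_layout`: a list with `names`
#'   (channel labels), `pos2d` (n x 2 matrix of positions in [-1, 1]),
#'   `neighbors` (list of integer vectors of neighbour indices), and
#'   `region` (character vector of region labels).
#' @examples
#' lay <- gen_layout(32, seed = 1)
#' table(lay$region)
#' @export
gen_layout <- function(n_channels, seed = 1L, neighbor_factor = 1.6) {
  if (n_channels < 16)
    stop("n_channels must be >= 16 to populate all scalp regions")
  set.seed(as.integer(seed))

  # sunflower spiral on the unit disc + jitter
  i <- seq_len(n_channels)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n_channels)
  th <- i * golden
  jit <- 0.25 / sqrt(n_channels)
  x <- r * cos(th) + stats::rnorm(n_channels, 0, jit)
  y <- r * sin(th) + stats::rnorm(n_channels, 0, jit)
  # keep everything inside the disc
  rr <- sqrt(x^2 + y^2)
  out <- rr > 1
  x[out] <- x[out] / rr[out]
  y[out] <- y[out] / rr[out]
  pos <- cbind(x = x, y = y)

  region <- assign_regions(pos)
  missing <- setdiff(scalp_regions(), unique(region))
  if (length(missing))
    stop("layout leaves region(s) empty: ", paste(missing, collapse = ", "),
         "; increase n_channels")

  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  thr <- neighbor_factor * stats::median(nn)
  adj <- d <= thr
  # guarantee >= 1 neighbour: link each sensor to its nearest one
  nearest <- apply(d, 1, which.min)
  for (k in seq_len(n_channels)) {
    adj[k, nearest[k]] <- TRUE
    adj[nearest[k], k] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  neighbors <- lapply(seq_len(n_channels),
                      function(k) as.integer(which(adj[k, ])))

  structure(
    list(names = sprintf("E%03d", i), pos2d = pos,
         neighbors = neighbors, region = region),
    class = "reach_layout")
}

scalp_regions <- function() {
  c("frontal", "central", "centro-parietal", "parieto-occipital",
    "occipital", "temporal")
}

# Region bands run anterior (y = +1) to posterior (y = -1). Lateral
# sensors in the mid band are temporal; the rest are split into five
# anterior-posterior bands by y rank, which keeps every region populated
# for any n >= 16 regardless of the jitter realization.
assign_regions <- function(pos) {
  n <- nrow(pos)
  y <- pos[, 2]
  x <- pos[, 1]
  region <- character(n)
  mid <- y <= 0.45 & y > -0.55
  temporal <- mid & abs(x) > 0.72
  if (sum(temporal) < 2) {
    cand <- which(mid)
    temporal[cand[order(-abs(x[cand]))[seq_len(min(2, length(cand)))]]] <-
      TRUE
  }
  region[temporal] <- "temporal"
  rest <- which(!temporal)
  bands <- c("occipital", "parieto-occipital", "centro-parietal",
             "central", "frontal")
  grp <- cut(rank(y[rest], ties.method = "first"), 5, labels = FALSE)
  region[rest] <- bands[grp]
  region
}

#' Indices of the channels in one or more scalp regions
#'
#' @param layout A `reach_layout`.
#' @param regions Character vector of region labels.
#' @return Integer vector of channel indices.
#' @export
region_channels <- function(layout, regions) {
  bad <- setdiff(regions, scalp_regions())
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  which(layout$region %in% regions)
}

#' @exportS3Method base::print
print.reach_layout <- function(x, ...) {
  cat(sprintf("<reach_layout> %d channels\n", length(x$names)))
  print(table(x$region))
  invisible(x)
}
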
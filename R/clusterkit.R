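## clusterkit: density-based clustering of localizations and per-cluster
## morphology, plus nearest-neighbor local-density mapping.
##
## Coordinates are unit-agnostic: eps and all distances are interpreted in
## whatever units the points carry. The pipeline passes micrometers so that
## the conventional eps = 0.3 applies; hand the function nm and eps means nm.

# grid index: cells of size `cell`; returns lookup giving point indices per
# cell and a function neighbors(i) -> indices of points in the 3x3 block
make_grid <- function(pts, cell) {
  cx <- as.integer(floor(pts[, 1] / cell))
  cy <- as.integer(floor(pts[, 2] / cell))
  key <- paste(cx, cy)
  cells <- split(seq_len(nrow(pts)), key)
  list(cx = cx, cy = cy, cells = cells)
}

grid_block <- function(grid, cx, cy, r = 1L) {
  ks <- as.vector(outer((cx - r):(cx + r), (cy - r):(cy + r),
                        function(a, b) paste(a, b)))
  unlist(grid$cells[ks], use.names = FALSE)
}

# exact eps-neighbor lists (self included) for every point, computed one grid
# cell at a time so the pairwise-distance work is vectorized
neighbor_lists <- function(pts, eps) {
  n <- nrow(pts)
  grid <- make_grid(pts, eps)
  out <- vector("list", n)
  eps2 <- eps^2
  for (ck in names(grid$cells)) {
    m <- grid$cells[[ck]]
    i1 <- m[1L]
    cand <- grid_block(grid, grid$cx[i1], grid$cy[i1])
    d2 <- outer(pts[m, 1], pts[cand, 1], "-")^2 +
          outer(pts[m, 2], pts[cand, 2], "-")^2
    hit <- d2 <= eps2
    for (j in seq_along(m)) out[[m[j]]] <- cand[hit[j, ]]
  }
  out
}

#' DBSCAN clustering
#'
#' Standard density-based clustering: a core point has at least `min_pts`
#' neighbors within `eps` (itself included); clusters are maximal
#' density-connected sets; points in no cluster are noise. Neighbor queries
#' use an exact grid index (results identical to brute force).
#'
#' @param points n x 2 matrix or data.frame with `x`, `y` columns. Units are
#'   taken as-is; `eps` is in the same units.
#' @param eps neighborhood radius (default 0.3, the conventional setting for
#'   coordinates in micrometers).
#' @param min_pts minimum neighborhood size for a core point (default 5).
#' @return integer labels, one per point: clusters are contiguous integers
#'   from 0, noise is -1.
#' @export
dbscan_cluster <- function(points, eps = 0.3, min_pts = 5) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  if (eps <= 0) stop_invalid("eps must be > 0")
  if (min_pts < 1) stop_invalid("min_pts must be >= 1")
  nb <- neighbor_lists(pts, eps)
  labels <- rep(-2L, n)        # -2 unvisited, -1 noise, >= 0 cluster id
  cl <- -1L
  for (p in seq_len(n)) {
    if (labels[p] != -2L) next
    np <- nb[[p]]
    if (length(np) < min_pts) { labels[p] <- -1L; next }
    cl <- cl + 1L
    labels[p] <- cl
    queue <- setdiff(np, p)
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      if (labels[q] == -1L) labels[q] <- cl           # border point
      if (labels[q] != -2L) next
      labels[q] <- cl
      nq <- nb[[q]]
      if (length(nq) >= min_pts) {
        queue <- c(queue, nq[labels[nq] == -2L | labels[nq] == -1L])
      }
    }
  }
  labels
}

#' Exact nearest-neighbor distances
#'
#' Euclidean distance from each point to its nearest distinct point, via an
#' exact expanding grid search (identical to brute force).
#'
#' @param points n x 2 coordinates (n >= 2).
#' @return numeric vector of NN distances.
#' @export
nn_distances <- function(points) {
  pts <- as_xy(points)
  n <- nrow(pts)
  if (n < 2) stop_insufficient("need at least 2 points for NN distances")
  if (n <= 800) {                       # brute force is fastest at small n
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    return(unname(apply(d, 1, min)))
  }
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-12)
  cell <- max(span / max(4, ceiling(sqrt(n))), 1e-12)
  grid <- make_grid(pts, cell)
  out <- rep(Inf, n)
  # first pass: per-cell vectorized search of the 3x3 block
  for (ck in names(grid$cells)) {
    m <- grid$cells[[ck]]
    cand <- grid_block(grid, grid$cx[m[1L]], grid$cy[m[1L]])
    d2 <- outer(pts[m, 1], pts[cand, 1], "-")^2 +
          outer(pts[m, 2], pts[cand, 2], "-")^2
    d2[cbind(seq_along(m), match(m, cand))] <- Inf   # exclude self
    out[m] <- sqrt(apply(d2, 1, min))
  }
  # the 3x3 block certainly covers radius `cell`; points whose tentative NN
  # is farther need an expanding exact search
  rmax <- as.integer(ceiling(span / cell)) + 1L
  for (i in which(out > cell)) {
    best <- out[i]^2
    r <- 2L
    repeat {
      cand <- grid_block(grid, grid$cx[i], grid$cy[i], r)
      cand <- cand[cand != i]
      if (length(cand)) {
        d2 <- (pts[cand, 1] - pts[i, 1])^2 + (pts[cand, 2] - pts[i, 2])^2
        best <- min(best, min(d2))
      }
      # a block of ring radius r covers Euclidean radius (r-1)*cell
      if (is.finite(best) && sqrt(best) <= (r - 1L) * cell) break
      if (r > rmax) break
      r <- r + 1L
    }
    out[i] <- sqrt(best)
  }
  out
}

hull_area <- function(xy) {
  h <- grDevices::chull(xy)
  if (length(h) < 3) return(0)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Per-cluster morphology statistics
#'
#' For every cluster of a labeling: member count, convex-hull area, axis
#' lengths (4 sqrt of the coordinate-covariance eigenvalues, i.e. full
#' widths), eccentricity in both conventions, and the mean within-cluster NN
#' distance. Areas and distances are in the squared/base units of the input
#' coordinates. Clusters with fewer than 3 members (or collinear members)
#' get zero area; eccentricity is undefined (NA) below 3 members and
#' degenerate (axis ratio 0) for collinear clusters.
#'
#' @param points n x 2 coordinates.
#' @param labels integer labels from [dbscan_cluster()] (-1 = noise).
#' @return a `cluster_result`: list with `per_cluster` data.frame (columns
#'   `cluster`, `n`, `area`, `major_axis`, `minor_axis`, `axis_ratio`
#'   = minor/major in [0,1], `eccentricity` = sqrt(1 - ratio^2), `mean_nn`),
#'   `n_clusters`, `fraction_clustered`, and the input `labels`.
#' @export
cluster_metrics <- function(points, labels) {
  pts <- as_xy(points)
  stopifnot(length(labels) == nrow(pts))
  ids <- sort(unique(labels[labels >= 0]))
  rows <- lapply(ids, function(cid) {
    m <- pts[labels == cid, , drop = FALSE]
    n <- nrow(m)
    area <- if (n >= 3) hull_area(m) else 0
    if (n >= 2) {
      ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
    } else {
      major <- minor <- 0
    }
    ratio <- if (n >= 3 && major > 0) minor / major else NA_real_
    ecc <- if (!is.na(ratio)) sqrt(max(0, 1 - ratio^2)) else NA_real_
    mean_nn <- if (n >= 2) mean(nn_distances(m)) else NA_real_
    data.frame(cluster = cid, n = n, area = area,
               major_axis = major, minor_axis = minor,
               axis_ratio = ratio, eccentricity = ecc, mean_nn = mean_nn)
  })
  per_cluster <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), n = integer(0), area = numeric(0),
               major_axis = numeric(0), minor_axis = numeric(0),
               axis_ratio = numeric(0), eccentricity = numeric(0),
               mean_nn = numeric(0))
  structure(list(per_cluster = per_cluster,
                 n_clusters = length(ids),
                 fraction_clustered = if (length(labels)) mean(labels >= 0) else NA_real_,
                 labels = labels),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster result: %d clusters, %.2f%% of %d points clustered\n",
              x$n_clusters, 100 * x$fraction_clustered, length(x$labels)))
  if (x$n_clusters) {
    cat(sprintf("  mean area %.4g, mean axis ratio %.3f, mean within-cluster NN %.4g\n",
                mean(x$per_cluster$area), mean(x$per_cluster$axis_ratio, na.rm = TRUE),
                mean(x$per_cluster$mean_nn, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.cluster_result <- function(object, ...) {
  print(object)
  if (object$n_clusters) {
    cat("Per-cluster area quantiles:\n")
    print(stats::quantile(object$per_cluster$area, c(0.05, 0.25, 0.5, 0.75, 0.95)))
  }
  invisible(object)
}

#' Nearest-neighbor local-density map
#'
#' For each cluster, the mean within-cluster NN distance `D_c` sets a
#' cluster-scaled radius `radius_scale * D_c`; each member's local density is
#' the number of cluster mates within that radius (self excluded). Noise
#' points get NA throughout.
#'
#' @param points n x 2 coordinates.
#' @param labels labels from [dbscan_cluster()].
#' @param radius_scale multiplier on the cluster mean NN distance (default 5).
#' @return a `density_map` data.frame: `label`, `nn_dist`, `neighbor_count`,
#'   `cluster_mean_nn`, `radius`.
#' @export
local_density_map <- function(points, labels, radius_scale = 5) {
  pts <- as_xy(points)
  stopifnot(length(labels) == nrow(pts))
  if (radius_scale <= 0) stop_invalid("radius_scale must be > 0")
  n <- nrow(pts)
  nn <- rep(NA_real_, n); cnt <- rep(NA_real_, n)
  dcn <- rep(NA_real_, n); rad <- rep(NA_real_, n)
  for (cid in unique(labels[labels >= 0])) {
    idx <- which(labels == cid)
    if (length(idx) < 2) next
    m <- pts[idx, , drop = FALSE]
    nnc <- nn_distances(m)
    dc <- mean(nnc)
    r <- radius_scale * dc
    d2 <- as.matrix(stats::dist(m))^2
    cnt[idx] <- colSums(d2 <= r^2) - 1L
    nn[idx] <- nnc
    dcn[idx] <- dc
    rad[idx] <- r
  }
  structure(data.frame(label = labels, nn_dist = nn, neighbor_count = cnt,
                       cluster_mean_nn = dcn, radius = rad),
            radius_scale = radius_scale,
            class = c("density_map", "data.frame"))
}

#' Highlight mask at a multiple of the cluster mean NN distance
#'
#' TRUE where a member's NN distance is at most `k` times its cluster's mean
#' NN distance (default k = 5); NA for noise points.
#'
#' @param density_map a `density_map` from [local_density_map()].
#' @param k threshold multiplier.
#' @return logical vector.
#' @export
highlight_threshold <- function(density_map, k = 5) {
  if (k <= 0) stop_invalid("k must be > 0")
  ifelse(is.na(density_map$nn_dist), NA,
         density_map$nn_dist <= k * density_map$cluster_mean_nn)
}
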
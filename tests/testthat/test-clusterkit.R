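test_that("DBSCAN defaults and simple geometries behave canonically", {
  expect_equal(formals(dbscan_cluster)$eps, 0.3)
  expect_equal(formals(dbscan_cluster)$min_pts, 5)
  expect_equal(dbscan_cluster(cbind(numeric(0), numeric(0))), integer(0))

  # two tight groups of 6, far apart: two clusters, no noise
  set.seed(40)
  g1 <- cbind(runif(6, 0, 0.01), runif(6, 0, 0.01))
  g2 <- cbind(runif(6, 5, 5.01), runif(6, 5, 5.01))
  lab <- dbscan_cluster(rbind(g1, g2), eps = 0.3, min_pts = 5)
  expect_equal(sort(unique(lab)), c(0L, 1L))
  expect_equal(length(unique(lab[1:6])), 1)
  expect_equal(length(unique(lab[7:12])), 1)
  expect_false(any(lab == -1L))

  # an isolated point is noise
  lab2 <- dbscan_cluster(rbind(g1, c(50, 50)), eps = 0.3, min_pts = 5)
  expect_equal(lab2[7], -1L)
})

test_that("DBSCAN labels match brute-force density reachability", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(20:100, 1)
    # mixed densities: a few tight blobs plus uniform background
    nb <- sample(1:3, 1)
    pts <- do.call(rbind, c(
      lapply(seq_len(nb), function(j) {
        c0 <- runif(2, 0, 10)
        cbind(rnorm(8, c0[1], 0.15), rnorm(8, c0[2], 0.15))
      }),
      list(cbind(runif(n, 0, 10), runif(n, 0, 10)))))
    eps <- runif(1, 0.2, 0.8)
    min_pts <- sample(3:6, 1)
    labels <- dbscan_cluster(pts, eps, min_pts)
    expect_dbscan_matches(labels, pts, eps, min_pts)
  }
})

test_that("cluster metrics capture shape, area and degeneracy", {
  # points on a circle: isotropic, axis ratio 1, standard eccentricity 0
  th <- seq(0, 2 * pi, length.out = 37)[-37]
  circ <- cbind(cos(th), sin(th))
  cm <- cluster_metrics(circ, rep(0L, 36))
  expect_equal(cm$per_cluster$axis_ratio, 1, tolerance = 1e-6)
  expect_equal(cm$per_cluster$eccentricity, 0, tolerance = 1e-3)

  # collinear points: degenerate ratio 0, zero hull area
  lin <- cbind(1:10, 2 * (1:10))
  cml <- cluster_metrics(lin, rep(0L, 10))
  expect_equal(cml$per_cluster$axis_ratio, 0, tolerance = 1e-9)
  expect_equal(cml$per_cluster$area, 0)

  # unit square corners: hull area 1
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(cluster_metrics(sq, rep(0L, 4))$per_cluster$area, 1)

  # anisotropic Gaussian, sd 100 x 50: axis ratio near 0.5
  set.seed(42)
  g <- cbind(rnorm(500, 0, 100), rnorm(500, 0, 50))
  cmg <- cluster_metrics(g, rep(0L, 500))
  expect_lt(abs(cmg$per_cluster$axis_ratio - 0.5) / 0.5, 0.15)
  expect_equal(cmg$per_cluster$eccentricity,
               sqrt(1 - cmg$per_cluster$axis_ratio^2))

  # tiny clusters: no area, undefined eccentricity
  cm2 <- cluster_metrics(cbind(c(0, 1), c(0, 1)), c(0L, 0L))
  expect_equal(cm2$per_cluster$area, 0)
  expect_true(is.na(cm2$per_cluster$axis_ratio))
})

test_that("metrics are invariant under rotation and translation", {
  set.seed(43)
  pts <- rbind(cbind(rnorm(40, 2, 0.1), rnorm(40, 2, 0.05)),
               cbind(rnorm(40, 8, 0.08), rnorm(40, 8, 0.08)))
  lab <- dbscan_cluster(pts, eps = 0.3, min_pts = 5)
  base <- cluster_metrics(pts, lab)
  th <- 0.83
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(rot, 2, c(12.3, -4.5), `+`)
  after <- cluster_metrics(moved, lab)
  expect_equal(after$per_cluster$area, base$per_cluster$area, tolerance = 1e-8)
  expect_equal(after$per_cluster$axis_ratio, base$per_cluster$axis_ratio,
               tolerance = 1e-8)
  expect_equal(after$per_cluster$mean_nn, base$per_cluster$mean_nn,
               tolerance = 1e-8)
})

test_that("nearest-neighbor distances are exact", {
  expect_error(nn_distances(cbind(1, 1)), class = "paintkit_insufficient_data")

  # two points 30 apart
  expect_equal(nn_distances(cbind(c(0, 30), c(0, 0))), c(30, 30))

  # regular grid of pitch p: all NN distances p
  p <- 2.5
  g <- as.matrix(expand.grid(x = (0:9) * p, y = (0:9) * p))
  expect_true(all(abs(nn_distances(g) - p) < 1e-12))

  # random sets match O(n^2) brute force, both code paths
  set.seed(44)
  for (n in c(100, 1200)) {
    pts <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    d <- as.matrix(dist(pts)); diag(d) <- Inf
    expect_equal(nn_distances(pts), unname(apply(d, 1, min)), tolerance = 1e-12)
  }
})

test_that("local density maps count scaled-radius neighbors exactly", {
  # two mutual neighbors closer than the scaled radius: density 1 each
  two <- cbind(c(0, 1), c(0, 0))
  dm <- local_density_map(two, c(0L, 0L), radius_scale = 5)
  expect_equal(dm$neighbor_count, c(1, 1))
  expect_equal(dm$cluster_mean_nn, c(1, 1))

  # uniform grid: interior members all see the same neighborhood
  p <- 1
  g <- as.matrix(expand.grid(x = 0:7, y = 0:7))
  dmg <- local_density_map(g, rep(0L, 64), radius_scale = 2)
  interior <- g[, 1] >= 2 & g[, 1] <= 5 & g[, 2] >= 2 & g[, 2] <= 5
  expect_equal(length(unique(dmg$neighbor_count[interior])), 1)

  # random cluster matches brute-force counting
  set.seed(45)
  pts <- cbind(rnorm(60), rnorm(60))
  lab <- rep(0L, 60)
  dmr <- local_density_map(pts, lab, radius_scale = 3)
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  nn <- apply(d, 1, min)
  r <- 3 * mean(nn)
  expect_equal(dmr$nn_dist, unname(nn))
  expect_equal(dmr$neighbor_count, unname(rowSums(d <= r)))

  # noise points carry NA
  dmn <- local_density_map(rbind(pts, c(100, 100)), c(lab, -1L), radius_scale = 3)
  expect_true(is.na(dmn$neighbor_count[61]))
})

test_that("highlighting thresholds on multiples of the cluster mean NN", {
  expect_equal(formals(highlight_threshold)$k, 5)
  # equidistant points are all highlighted
  p <- 1
  g <- as.matrix(expand.grid(x = 0:4, y = 0:4))
  dm <- local_density_map(g, rep(0L, 25))
  expect_true(all(highlight_threshold(dm)))
  # a point beyond 5x the cluster mean NN distance is excluded
  line <- cbind(c(0, 1, 2, 3, 4, 44), rep(0, 6))   # outlier NN = 40 > 5 * 7.5
  dml <- local_density_map(line, rep(0L, 6))
  hl <- highlight_threshold(dml, k = 5)
  expect_false(hl[6])
  expect_true(all(hl[1:5]))
})

test_that("simulated clutch scenes are recovered cluster for cluster", {
  sc <- make_clutch_scene(120, 40, 50, fov = c(60000, 60000), seed = 50)
  pts <- cbind(sc$sites$x, sc$sites$y) / 1000    # nm -> um
  lab <- dbscan_cluster(pts, eps = 0.3, min_pts = 5)
  cm <- cluster_metrics(pts, lab)
  expect_gt(cm$fraction_clustered, 0.99)
  expect_lt(abs(cm$n_clusters - 120), 0.02 * 120 + 1)
  # recovered hull areas match the true per-group footprint
  truth <- vapply(split(seq_len(nrow(pts)), sc$sites$structure_id), function(i) {
    xy <- pts[i, , drop = FALSE]
    h <- grDevices::chull(xy)
    abs(sum(xy[h, 1] * xy[c(h[-1], h[1]), 2] - xy[c(h[-1], h[1]), 1] * xy[h, 2])) / 2
  }, 0)
  expect_lt(abs(mean(cm$per_cluster$area) - mean(truth)) / mean(truth), 0.3)
})
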
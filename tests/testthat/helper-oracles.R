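# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately share no code with the implementation.

# O(n^2) DBSCAN by direct density reachability. Returns a list with
# `labels` (cluster ids from 0, -1 noise, following the convention of the
# package) and `border_options`: for each point, the set of cluster ids it
# could legally belong to (border points adjacent to several clusters are
# ambiguous under any DBSCAN ordering).
brute_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  nbr <- d <= eps
  core <- rowSums(nbr) >= min_pts     # self included on the diagonal
  labels <- rep(-1L, n)
  cl <- -1L
  for (p in which(core)) {
    if (labels[p] >= 0L) next
    cl <- cl + 1L
    frontier <- p
    labels[p] <- cl
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(q) which(nbr[q, ] & core))))
      nxt <- nxt[labels[nxt] < 0L]
      labels[nxt] <- cl
      frontier <- nxt
    }
  }
  border_options <- vector("list", n)
  for (p in seq_len(n)) {
    if (core[p]) {
      border_options[[p]] <- labels[p]
    } else {
      opts <- unique(labels[nbr[p, ] & core])
      border_options[[p]] <- if (length(opts)) opts else -1L
    }
  }
  core_labels <- labels
  core_labels[!core] <- NA_integer_
  list(core = core, core_labels = core_labels, border_options = border_options)
}

# check a labeling against the brute-force oracle up to relabeling
expect_dbscan_matches <- function(labels, pts, eps, min_pts) {
  oracle <- brute_dbscan(pts, eps, min_pts)
  # core points: cluster partition must be identical up to renaming
  co <- oracle$core
  expect_true(all(labels[co] >= 0L))
  map <- tapply(labels[co], oracle$core_labels[co], unique)
  expect_true(all(lengths(map) == 1L))               # oracle cluster -> one label
  expect_equal(length(unique(unlist(map))), length(map))  # and injectively
  lookup <- unlist(map)
  # non-core points: label must be one of the oracle's legal options
  for (p in which(!co)) {
    opts <- oracle$border_options[[p]]
    legal <- if (identical(opts, -1L)) -1L else unname(lookup[as.character(opts)])
    expect_true(labels[p] %in% legal)
  }
  invisible(labels)
}

# minimal localization table from bare coordinates
quick_table <- function(x, y, frame = seq_along(x), uncertainty = 20,
                        exposure = 0.05, fov = c(max(x, 0) + 100, max(y, 0) + 100)) {
  loc_table(data.frame(frame = frame, x = x, y = y,
                       uncertainty = rep_len(uncertainty, length(x))),
            exposure = exposure, fov = fov)
}

# render one pixel-integrated Gaussian emitter into a photon-count frame
render_emitter <- function(nc, nr, x0, y0, n_photons, psf_sigma, pixel_size,
                           background = 0, poisson = FALSE) {
  gx <- diff(stats::pnorm((0:nc) * pixel_size, x0, psf_sigma))
  gy <- diff(stats::pnorm((0:nr) * pixel_size, y0, psf_sigma))
  img <- n_photons * (gy %o% gx) + background
  if (poisson) img <- matrix(stats::rpois(nr * nc, img), nr, nc)
  img
}
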
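## simkit: ground-truth scenes, binding kinetics and synthetic acquisitions.
##
## The simulator emulates transient-binding (PAINT-style) live-cell SMLM:
## fixed binding sites arranged either in nanoscale clusters ("clutch"-like
## nuclear targets) or along motile tubes (mitochondria-like cytoplasmic
## targets); binders arrive at each site as a Poisson process and stay bound
## for an exponentially distributed residence time; each bound interval shows
## up in every camera frame it sufficiently overlaps, either directly as a
## localization with a known precision, or as photons rendered into camera
## frames.

#' Kinetics and acquisition parameters
#'
#' @param site_on_rate binding events per second per site. The default is a
#'   plausible PAINT regime, not a measured constant.
#' @param mean_residence mean bound time in seconds (residence times are
#'   exponential). Plausible default, not a measured constant.
#' @param photon_rate emitted photons per second while bound.
#' @param duration total acquisition in seconds. Default 200 s.
#' @param exposure camera exposure per frame in seconds. Default 0.05 s, so
#'   the default acquisition is 4000 frames.
#' @return a `kinetics_params` list; `n_frames = floor(duration/exposure)`.
#' @export
kinetics_params <- function(site_on_rate = 0.02, mean_residence = 0.1,
                            photon_rate = 20000, duration = 200, exposure = 0.05) {
  for (v in c(mean_residence = mean_residence, photon_rate = photon_rate,
              duration = duration, exposure = exposure)) {
    if (!is.finite(v) || v <= 0) stop_invalid("kinetics parameters must be strictly positive")
  }
  if (!is.finite(site_on_rate) || site_on_rate < 0) {
    stop_invalid("site_on_rate must be non-negative")
  }
  structure(list(site_on_rate = site_on_rate, mean_residence = mean_residence,
                 photon_rate = photon_rate, duration = duration, exposure = exposure,
                 n_frames = as.integer(floor(duration / exposure))),
            class = "kinetics_params")
}

#' Camera model for frame rendering
#'
#' @param pixel_size nm per pixel.
#' @param psf_sigma PSF standard deviation in nm.
#' @param background_rate uniform background, photons per pixel per frame.
#' @param frame_shape `c(rows, cols)`; default just covers the scene fov.
#' @param fov fov used to derive `frame_shape` when it is NULL.
#' @export
camera_model <- function(pixel_size = 100, psf_sigma = 150, background_rate = 10,
                         frame_shape = NULL, fov = NULL) {
  if (pixel_size <= 0 || psf_sigma <= 0 || background_rate < 0) {
    stop_invalid("camera parameters out of range")
  }
  if (is.null(frame_shape)) {
    if (is.null(fov)) stop_invalid("give frame_shape or fov")
    frame_shape <- as.integer(ceiling(rev(fov) / pixel_size))  # rows from height
  }
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 background_rate = background_rate,
                 frame_shape = as.integer(frame_shape)),
            class = "camera_model")
}

new_scene <- function(sites, fov, motion, scene_kind) {
  structure(list(sites = sites, fov = fov, motion = motion, scene_kind = scene_kind),
            class = "gt_scene")
}

#' @export
print.gt_scene <- function(x, ...) {
  cat(sprintf("Ground-truth scene (%s): %d sites, %d structures, fov %g x %g nm, %s\n",
              x$scene_kind, nrow(x$sites), length(unique(x$sites$structure_id)),
              x$fov[1], x$fov[2],
              if (is.null(x$motion)) "static" else "with motion"))
  invisible(x)
}

# displacement of each structure id at time t (n x 2 matrix, nm)
scene_displacement <- function(scene, structure_id, t) {
  if (is.null(scene$motion)) {
    matrix(0, length(structure_id), 2)
  } else {
    scene$motion(structure_id, t)
  }
}

#' Simulate a clustered ("clutch"-like) scene of binding sites
#'
#' Cluster centers are uniform over the field of view (inset by 3 sigma so
#' clusters fit); sites are isotropic Gaussian around their center. Emulates
#' nuclear targets organized into dense nanodomains.
#'
#' @param n_clusters number of clusters (>= 1).
#' @param sites_per_cluster binding sites per cluster.
#' @param cluster_sigma isotropic sd of sites about the center, nm.
#' @param fov `c(width, height)` in nm.
#' @param seed RNG seed.
#' @return a `gt_scene` with `structure_id` = cluster index (0-based).
#' @export
make_clutch_scene <- function(n_clusters, sites_per_cluster, cluster_sigma,
                              fov = c(20000, 20000), seed = 1) {
  if (n_clusters < 1) stop_invalid("n_clusters must be >= 1")
  if (sites_per_cluster < 1) stop_invalid("sites_per_cluster must be >= 1")
  if (cluster_sigma <= 0) stop_invalid("cluster_sigma must be > 0")
  margin <- 3 * cluster_sigma
  if (any(fov <= 2 * margin)) {
    stop_invalid("fov too small to contain clusters of sd ", cluster_sigma, " nm")
  }
  with_seed(substream_seed(seed, "clutch"), {
    cx <- stats::runif(n_clusters, margin, fov[1] - margin)
    cy <- stats::runif(n_clusters, margin, fov[2] - margin)
    n <- n_clusters * sites_per_cluster
    id <- rep.int(seq_len(n_clusters) - 1L, rep.int(sites_per_cluster, n_clusters))
    x <- rep(cx, each = sites_per_cluster) + stats::rnorm(n, 0, cluster_sigma)
    y <- rep(cy, each = sites_per_cluster) + stats::rnorm(n, 0, cluster_sigma)
    # redraw the rare site that falls outside the fov (margin is 3 sigma)
    for (i in 1:100) {
      out <- x < 0 | x > fov[1] | y < 0 | y > fov[2]
      if (!any(out)) break
      x[out] <- cx[id[out] + 1L] + stats::rnorm(sum(out), 0, cluster_sigma)
      y[out] <- cy[id[out] + 1L] + stats::rnorm(sum(out), 0, cluster_sigma)
    }
    x <- pmin(pmax(x, 0), fov[1]); y <- pmin(pmax(y, 0), fov[2])
    new_scene(data.frame(x = x, y = y, structure_id = id), fov, NULL, "clutch")
  })
}

# natural cubic path through control points, arc-parameterized approximately
tube_path <- function(ctrl) {
  s <- seq(0, 1, length.out = nrow(ctrl))
  fx <- stats::splinefun(s, ctrl[, 1], method = "natural")
  fy <- stats::splinefun(s, ctrl[, 2], method = "natural")
  list(fx = fx, fy = fy)
}

#' Simulate a scene of elongated, optionally motile, tube-like structures
#'
#' Each tube is a smooth random cubic path through 4-8 uniform control
#' points; sites scatter about the path with transverse Gaussian sd
#' `tube_sigma`. When `drift_speed > 0` each tube additionally carries a
#' smooth rigid displacement over time: straight drift at `drift_speed` in a
#' random direction plus a small transverse sinusoidal wobble. Emulates
#' motile mitochondria imaged over minutes.
#'
#' @param n_tubes number of tubes (>= 1).
#' @param tube_sigma transverse sd about the tube axis, nm.
#' @param sites_per_tube binding sites per tube.
#' @param drift_speed mean drift speed, nm/s (0 for a static scene).
#' @param fov `c(width, height)` nm.
#' @param seed RNG seed.
#' @param control_points optional list (one matrix of x,y control points per
#'   tube) overriding the random paths; used for controlled geometries.
#' @param wobble_amp,wobble_period amplitude (nm) and period (s) of the
#'   transverse wobble added on top of the drift.
#' @return a `gt_scene` with a `motion` function unless the scene is static.
#' @export
make_tube_scene <- function(n_tubes, tube_sigma, sites_per_tube, drift_speed = 0,
                            fov = c(20000, 20000), seed = 1,
                            control_points = NULL,
                            wobble_amp = 50, wobble_period = 60) {
  if (n_tubes < 1) stop_invalid("n_tubes must be >= 1")
  if (tube_sigma <= 0) stop_invalid("tube_sigma must be > 0")
  margin <- 3 * tube_sigma
  if (any(fov <= 2 * margin)) stop_invalid("fov too small for tube_sigma ", tube_sigma)
  with_seed(substream_seed(seed, "tube"), {
    xs <- ys <- id <- NULL
    for (k in seq_len(n_tubes)) {
      ctrl <- if (!is.null(control_points)) {
        as.matrix(control_points[[k]])
      } else {
        np <- sample(4:8, 1)
        cbind(sort(stats::runif(np, margin, fov[1] - margin)),
              stats::runif(np, margin, fov[2] - margin))
      }
      pth <- tube_path(ctrl)
      u <- stats::runif(sites_per_tube)
      eps <- 1e-4
      dx <- pth$fx(u + eps) - pth$fx(u - eps)
      dy <- pth$fy(u + eps) - pth$fy(u - eps)
      nrm <- sqrt(dx^2 + dy^2); nrm[nrm == 0] <- 1
      off <- stats::rnorm(sites_per_tube, 0, tube_sigma)
      x <- pth$fx(u) - off * dy / nrm
      y <- pth$fy(u) + off * dx / nrm
      xs <- c(xs, pmin(pmax(x, 0), fov[1]))
      ys <- c(ys, pmin(pmax(y, 0), fov[2]))
      id <- c(id, rep.int(k - 1L, sites_per_tube))
    }
    motion <- NULL
    if (drift_speed > 0) {
      ang <- stats::runif(n_tubes, 0, 2 * pi)
      phase <- stats::runif(n_tubes, 0, 2 * pi)
      vx <- drift_speed * cos(ang); vy <- drift_speed * sin(ang)
      wx <- -sin(ang); wy <- cos(ang)     # transverse unit vectors
      motion <- function(structure_id, t) {
        i <- structure_id + 1L
        w <- wobble_amp * sin(2 * pi * t / wobble_period + phase[i])
        cbind(vx[i] * t + w * wx[i], vy[i] * t + w * wy[i])
      }
    }
    new_scene(data.frame(x = xs, y = ys, structure_id = id), fov, motion, "tube")
  })
}

#' Simulate stochastic binding events on a scene
#'
#' Per site, event start times follow a homogeneous Poisson process at
#' `site_on_rate` over the acquisition, and bound durations are i.i.d.
#' exponential with mean `mean_residence`.
#'
#' @param scene a `gt_scene`.
#' @param kinetics a `kinetics_params`.
#' @param seed RNG seed.
#' @return a `binding_trace`: data.frame (site, start, duration) sorted by
#'   start time; `site` is the 1-based row index into `scene$sites`.
#' @export
simulate_binding <- function(scene, kinetics, seed = 1) {
  stopifnot(inherits(scene, "gt_scene"), inherits(kinetics, "kinetics_params"))
  n_sites <- nrow(scene$sites)
  with_seed(substream_seed(seed, "binding"), {
    n_ev <- stats::rpois(n_sites, kinetics$site_on_rate * kinetics$duration)
    site <- rep.int(seq_len(n_sites), n_ev)
    start <- stats::runif(length(site), 0, kinetics$duration)
    duration <- stats::rexp(length(site), 1 / kinetics$mean_residence)
    ord <- order(start)
    structure(data.frame(site = site[ord], start = start[ord], duration = duration[ord]),
              seed = as.integer(seed), n_sites = n_sites,
              class = c("binding_trace", "data.frame"))
  })
}

# frames (1-based) a bound interval [start, start+duration) overlaps by at
# least `overlap_min` of the exposure; returns list(frame, overlap_s) vectors
event_frames <- function(start, duration, exposure, n_frames, overlap_min) {
  k0 <- pmax(1L, as.integer(floor(start / exposure)) + 1L)
  k1 <- pmin(n_frames, as.integer(floor((start + duration) / exposure)) + 1L)
  keep <- k1 >= k0
  idx <- which(keep)
  counts <- k1[idx] - k0[idx] + 1L
  ev <- rep.int(idx, counts)
  fr <- unlist(lapply(seq_along(idx), function(j) k0[idx[j]]:k1[idx[j]]), use.names = FALSE)
  if (is.null(fr)) fr <- integer(0)
  ov <- pmin(start[ev] + duration[ev], fr * exposure) - pmax(start[ev], (fr - 1) * exposure)
  sel <- if (overlap_min > 0) ov >= overlap_min * exposure else ov > 0
  list(event = ev[sel], frame = fr[sel], overlap = ov[sel])
}

#' Convert binding events directly to ground-truth localizations
#'
#' Direct mode: bypasses image rendering. Each event contributes one
#' localization to every frame it overlaps by at least `overlap_min` of the
#' exposure, at the (motion-displaced) site position plus isotropic Gaussian
#' error whose sd is the event's localization precision.
#'
#' @param scene,trace,kinetics scene, binding trace and kinetics used.
#' @param precision_model either a single number (constant precision, nm;
#'   default 20) or a function(n) returning n per-event precision draws.
#' @param seed RNG seed.
#' @param overlap_min minimum exposure-overlap fraction for a frame to count.
#' @param psf_sigma nominal PSF sd recorded in the `sigma` column, nm.
#' @return a `loc_table`.
#' @export
events_to_localizations <- function(scene, trace, kinetics, precision_model = 20,
                                    seed = 1, overlap_min = 0.5, psf_sigma = 150) {
  stopifnot(inherits(scene, "gt_scene"), inherits(kinetics, "kinetics_params"))
  if (nrow(trace) && max(trace$site) > nrow(scene$sites)) {
    stop_invalid("trace refers to sites absent from the scene")
  }
  ef <- event_frames(trace$start, trace$duration, kinetics$exposure,
                     kinetics$n_frames, overlap_min)
  n <- length(ef$frame)
  with_seed(substream_seed(seed, "localize"), {
    prec_ev <- if (is.function(precision_model)) {
      precision_model(nrow(trace))
    } else {
      rep.int(precision_model, nrow(trace))
    }
    if (any(prec_ev < 0)) stop_invalid("precision must be >= 0")
    prec <- prec_ev[ef$event]
    site <- trace$site[ef$event]
    tmid <- (ef$frame - 0.5) * kinetics$exposure
    disp <- matrix(0, n, 2)
    if (!is.null(scene$motion) && n > 0) {
      # rigid per-structure motion evaluated at each frame's mid-time
      for (tt in unique(tmid)) {
        i <- which(tmid == tt)
        disp[i, ] <- scene_displacement(scene, scene$sites$structure_id[site[i]], tt)
      }
    }
    x <- scene$sites$x[site] + disp[, 1] + stats::rnorm(n, 0, prec)
    y <- scene$sites$y[site] + disp[, 2] + stats::rnorm(n, 0, prec)
    rec <- data.frame(frame = ef$frame, x = x, y = y,
                      sigma = psf_sigma,
                      intensity = kinetics$photon_rate * ef$overlap,
                      offset = 0, bkgstd = 0,
                      # precision 0 means exact ground truth; keep it
                      # representable in the table (uncertainty must be > 0)
                      uncertainty = pmax(prec, 1e-9))
    loc_table(rec, pixel_size = NA_real_, exposure = kinetics$exposure, fov = scene$fov)
  })
}

# pixel-integrated 1-D Gaussian mass over pixels 1..n (edges at 0, a, 2a, ...)
pixel_gauss <- function(center_nm, sd_nm, pixel_size, n) {
  edges <- (0:n) * pixel_size
  diff(stats::pnorm(edges, center_nm, sd_nm))
}

#' Render binding events into a synthetic camera frame stack
#'
#' Per frame, each bound emitter deposits `photon_rate * (bound time within
#' the frame)` expected photons as a pixel-integrated 2D Gaussian of sd
#' `psf_sigma`, on top of a uniform Poisson background; pixel values are
#' Poisson samples of the expectation.
#'
#' @param scene,trace,kinetics as in [events_to_localizations()].
#' @param camera a `camera_model` covering the scene fov.
#' @param seed RNG seed.
#' @return a `frame_stack`: integer array `[rows, cols, n_frames]` with
#'   `pixel_size` and `exposure` attributes.
#' @export
render_stack <- function(scene, trace, kinetics, camera, seed = 1) {
  stopifnot(inherits(camera, "camera_model"))
  rows <- camera$frame_shape[1]; cols <- camera$frame_shape[2]
  if (cols * camera$pixel_size < scene$fov[1] || rows * camera$pixel_size < scene$fov[2]) {
    stop_invalid("camera frame does not cover the scene fov")
  }
  nf <- kinetics$n_frames
  ef <- event_frames(trace$start, trace$duration, kinetics$exposure, nf,
                     overlap_min = 0)   # any positive overlap deposits photons
  stack <- array(0L, dim = c(rows, cols, nf))
  with_seed(substream_seed(seed, "render"), {
    for (k in seq_len(nf)) {
      expected <- matrix(camera$background_rate, rows, cols)
      i <- which(ef$frame == k)
      if (length(i)) {
        tmid <- (k - 0.5) * kinetics$exposure
        site <- trace$site[ef$event[i]]
        disp <- scene_displacement(scene, scene$sites$structure_id[site], tmid)
        px <- scene$sites$x[site] + disp[, 1]
        py <- scene$sites$y[site] + disp[, 2]
        amp <- kinetics$photon_rate * ef$overlap[i]
        for (j in seq_along(i)) {
          gx <- pixel_gauss(px[j], camera$psf_sigma, camera$pixel_size, cols)
          gy <- pixel_gauss(py[j], camera$psf_sigma, camera$pixel_size, rows)
          expected <- expected + amp[j] * (gy %o% gx)
        }
      }
      stack[, , k] <- stats::rpois(rows * cols, expected)
    }
  })
  structure(stack, pixel_size = camera$pixel_size, exposure = kinetics$exposure,
            psf_sigma = camera$psf_sigma, class = "frame_stack")
}

#' Expected localization rate of a simulated acquisition
#'
#' A bound interval of mean length tau overlaps `tau/exposure + 1` frames on
#' average, but each of the two partial end frames only counts when its
#' overlap fraction reaches `overlap_min`, which removes `2 * overlap_min`
#' frames in expectation (random phase). The expected rate is therefore
#' `n_sites * site_on_rate * (tau/exposure + 1 - 2 * overlap_min)`
#' localizations per second; at the default half-frame rule this is simply
#' `n_sites * site_on_rate * tau/exposure`.
#'
#' @param scene,kinetics scene and kinetics.
#' @param overlap_min overlap threshold used in [events_to_localizations()].
#' @return localizations per second (scalar).
#' @export
expected_localization_rate <- function(scene, kinetics, overlap_min = 0.5) {
  nrow(scene$sites) * kinetics$site_on_rate *
    (kinetics$mean_residence / kinetics$exposure + 1 - 2 * overlap_min)
}

## ---- plain-text serialization ------------------------------------------

#' Write / read a scene as a tab-separated table
#'
#' One row per site with a `#`-prefixed header recording fov and scene kind.
#' Motion is a function and is not serialized: a scene read back is static.
#' @param scene a `gt_scene`; `path` file path.
#' @export
write_scene <- function(scene, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fov\t%g\t%g", scene$fov[1], scene$fov[2]), con)
  writeLines(sprintf("# scene_kind\t%s", scene$scene_kind), con)
  utils::write.table(scene$sites, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scene
#' @param path file path.
#' @export
read_scene <- function(path) {
  hdr <- readLines(path, n = 2L)
  fov <- as.numeric(strsplit(hdr[1], "\t")[[1]][2:3])
  kind <- strsplit(hdr[2], "\t")[[1]][2]
  sites <- utils::read.delim(path, skip = 2L)
  new_scene(sites, fov, NULL, kind)
}

#' Write / read a binding trace as a tab-separated table
#' @param trace a `binding_trace`; `path` file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param path file path.
#' @param n_sites number of sites in the parent scene.
#' @export
read_trace <- function(path, n_sites = NA_integer_) {
  df <- utils::read.delim(path)
  structure(df[order(df$start), ], n_sites = n_sites,
            class = c("binding_trace", "data.frame"))
}

#' Write / read a frame stack as multi-page 16-bit TIFF
#'
#' Counts are clipped to [0, 65535]; one page per frame.
#' @param stack a `frame_stack`; `path` file path.
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    pmin(pmax(stack[, , k], 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param path file path.
#' @param pixel_size,exposure acquisition metadata to attach (nm, s).
#' @export
read_stack_tiff <- function(path, pixel_size, exposure) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- as.integer(round(pages[[k]] * 65535))
  structure(stack, pixel_size = pixel_size, exposure = exposure,
            class = "frame_stack")
}
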
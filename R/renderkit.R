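## renderkit: super-resolution reconstructions and temporal renderings.

new_sr_image <- function(mat, render_bin, origin = c(0, 0), window = NULL) {
  structure(mat, render_bin = render_bin, origin = origin, time_window = window,
            class = c("sr_image", "matrix", "array"))
}

#' @export
print.sr_image <- function(x, ...) {
  w <- attr(x, "time_window")
  cat(sprintf("SR image %d x %d px at %g nm/px, mass %g%s\n",
              nrow(x), ncol(x), attr(x, "render_bin"), sum(x),
              if (is.null(w)) "" else sprintf(", window [%g, %g) s", w[1], w[2])))
  invisible(x)
}

#' @export
plot.sr_image <- function(x, ...) {
  graphics::image(t(x)[, nrow(x):1], col = grDevices::hcl.colors(64, "Inferno"),
                  asp = nrow(x) / ncol(x), axes = FALSE, ...)
  invisible(x)
}

# select records in the half-open time window [t0, t1)
window_rows <- function(table, window) {
  if (is.null(window)) rep(TRUE, nrow(table))
  else table$time >= window[1] & table$time < window[2]
}

#' Render a 2D count histogram of localizations
#'
#' Each localization adds one count to the bin containing it; the image mass
#' therefore equals the number of records rendered. Time windows are
#' half-open `[t0, t1)`.
#'
#' @param table a `loc_table`.
#' @param render_bin bin size in nm/px (default 10).
#' @param window optional `c(t0, t1)` time window in seconds.
#' @param fov field of view, nm; default from table metadata.
#' @return an `sr_image` (matrix of counts; rows = y, cols = x).
#' @export
render_histogram <- function(table, render_bin = 10, window = NULL,
                             fov = loc_fov(table)) {
  if (render_bin <= 0) stop_invalid("render_bin must be > 0")
  nc <- max(1L, as.integer(ceiling(fov[1] / render_bin)))
  nr <- max(1L, as.integer(ceiling(fov[2] / render_bin)))
  keep <- window_rows(table, window)
  x <- table$x[keep]; y <- table$y[keep]
  inside <- x >= 0 & x < fov[1] & y >= 0 & y < fov[2]
  ci <- pmin(as.integer(floor(x[inside] / render_bin)) + 1L, nc)
  ri <- pmin(as.integer(floor(y[inside] / render_bin)) + 1L, nr)
  m <- matrix(tabulate((ci - 1L) * nr + ri, nbins = nr * nc), nr, nc)
  new_sr_image(m, render_bin, window = window)
}

#' Render localizations as unit-mass Gaussians
#'
#' Display variant: each record deposits a pixel-integrated 2D Gaussian of
#' sd equal to its localization uncertainty. Total mass is conserved up to
#' edge truncation.
#'
#' @inheritParams render_histogram
#' @return an `sr_image` of summed Gaussian mass.
#' @export
render_gaussian <- function(table, render_bin = 10, window = NULL,
                            fov = loc_fov(table)) {
  if (render_bin <= 0) stop_invalid("render_bin must be > 0")
  nc <- max(1L, as.integer(ceiling(fov[1] / render_bin)))
  nr <- max(1L, as.integer(ceiling(fov[2] / render_bin)))
  m <- matrix(0, nr, nc)
  keep <- which(window_rows(table, window))
  for (i in keep) {
    sd_px <- max(table$uncertainty[i] / render_bin, 1e-6)
    cx <- table$x[i] / render_bin; cy <- table$y[i] / render_bin
    r <- ceiling(4 * sd_px)
    c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r))
    r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r))
    if (c0 > c1 || r0 > r1) next
    gx <- diff(stats::pnorm((c0 - 1):c1, cx, sd_px))
    gy <- diff(stats::pnorm((r0 - 1):r1, cy, sd_px))
    m[r0:r1, c0:c1] <- m[r0:r1, c0:c1] + gy %o% gx
  }
  new_sr_image(m, render_bin, window = window)
}

#' Maximum-intensity projection of a frame stack
#'
#' Per-pixel maximum over frames: the diffraction-limited time-integration
#' reference image for a super-resolution reconstruction.
#'
#' @param stack a `frame_stack` (array rows x cols x frames) or list of
#'   matrices.
#' @return matrix of per-pixel maxima.
#' @export
max_projection <- function(stack) {
  if (is.list(stack)) {
    if (!length(stack)) stop_invalid("empty stack")
    return(Reduce(pmax, stack))
  }
  d <- dim(stack)
  if (is.null(d) || length(d) != 3 || d[3] < 1) stop_invalid("empty stack")
  apply(stack, c(1, 2), max)
}

#' Map acquisition times to [0, 1] for temporal color-coding
#'
#' @param table a `loc_table` (or anything with a `time` column).
#' @param t_range `c(t0, t1)` seconds, t1 > t0.
#' @return numeric vector, `(time - t0)/(t1 - t0)` clipped to [0, 1].
#' @export
temporal_color_map <- function(table, t_range) {
  if (t_range[2] <= t_range[1]) stop_invalid("t_range must have t1 > t0")
  pmin(pmax((table$time - t_range[1]) / (t_range[2] - t_range[1]), 0), 1)
}

#' Moving-window reconstruction stack
#'
#' Renders histograms over sliding half-open windows
#' `[k*step, k*step + window)` for `k = 0 .. floor((T - window)/step)`,
#' the moving-average reconstruction used to visualize slow structural
#' dynamics. Defaults: 25 s window, 0.5 s increment.
#'
#' @param table a `loc_table`.
#' @param window window length, s.
#' @param step window increment, s.
#' @param render_bin nm/px.
#' @param duration total acquisition T in seconds; default the end of the
#'   last frame in the table.
#' @return list of `sr_image`, one per window, with `time_window` attributes.
#' @export
moving_window_stack <- function(table, window = 25, step = 0.5, render_bin = 10,
                                duration = NULL) {
  if (step <= 0) stop_invalid("step must be > 0")
  if (window <= 0) stop_invalid("window must be > 0")
  if (is.null(duration)) {
    duration <- if (nrow(table)) max(table$time) + loc_exposure(table) else 0
  }
  if (window > duration) stop_invalid("window exceeds the acquisition duration")
  ks <- 0:floor((duration - window) / step)
  lapply(ks, function(k) {
    render_histogram(table, render_bin, window = c(k * step, k * step + window))
  })
}

#' Write a rendered image (or list of images) as 16-bit TIFF
#'
#' Count images are clipped to [0, 65535]; one page per window for lists.
#'
#' @param img an `sr_image` or list of them.
#' @param path file path.
#' @export
write_render_tiff <- function(img, path) {
  pages <- if (is.list(img)) img else list(img)
  pages <- lapply(pages, function(m) {
    m <- unclass(m); attributes(m) <- list(dim = dim(m))
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
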
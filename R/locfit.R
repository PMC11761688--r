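## locfit: spot detection, sub-pixel 2D Gaussian fitting and the precision
## filter. Mirrors the standard SMLM localization chain (band-pass detection,
## least-squares Gaussian fit, Thompson-style precision estimate).
##
## Coordinate convention: x, y in nm, origin at the outer corner of pixel
## (row 1, col 1); the center of 1-based pixel (i, j) maps to
## ((j - 0.5) * pixel_size, (i - 0.5) * pixel_size). Frames are 1-based.

# separable Gaussian blur with edge replication; kernel radius is clamped to
# the frame so arbitrarily small frames stay valid
gauss_blur <- function(img, sigma) {
  r <- max(1L, min(ceiling(3 * sigma), nrow(img) - 1L, ncol(img) - 1L))
  k <- stats::dnorm(-r:r, 0, sigma); k <- k / sum(k)
  conv_cols <- function(m) {
    p <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nrow(m), r), , drop = FALSE])
    f <- stats::filter(p, k, sides = 2)
    matrix(f[(r + 1):(r + nrow(m)), ], nrow(m), ncol(m))
  }
  t(conv_cols(t(conv_cols(img))))
}

#' Detect candidate spots in one camera frame
#'
#' Difference-of-Gaussians band-pass followed by 3x3 local-maximum detection
#' at a robust threshold: a candidate must exceed
#' `median + peak_threshold * mad` of the filtered frame. Candidates closer
#' than half the fit window to a frame edge are dropped.
#'
#' @param frame_image photon-count matrix (rows = y, cols = x).
#' @param pixel_size nm per pixel.
#' @param band_sigmas band-pass sd pair `c(narrow, wide)` in nm; default one
#'   and two PSF widths.
#' @param peak_threshold threshold in units of the robust sd of the filtered
#'   frame.
#' @param window fit window edge length in px (odd); sets the edge margin.
#' @return integer matrix with columns `row`, `col` (1-based pixel indices).
#' @export
detect_spots <- function(frame_image, pixel_size, band_sigmas = c(150, 300),
                         peak_threshold = 4, window = 7) {
  if (any(frame_image < 0)) stop_invalid("frame must be non-negative")
  s <- band_sigmas / pixel_size
  f <- gauss_blur(frame_image, s[1]) - gauss_blur(frame_image, s[2])
  thr <- stats::median(f) + peak_threshold * stats::mad(f)
  nr <- nrow(f); nc <- ncol(f)
  if (nr < 3 || nc < 3) return(cbind(row = integer(0), col = integer(0)))
  core <- f[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & core >= f[2:(nr - 1) + di, 2:(nc - 1) + dj, drop = FALSE]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(cbind(row = integer(0), col = integer(0)))
  cand <- cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
  half <- window %/% 2
  keep <- cand[, 1] > half & cand[, 1] <= nr - half &
          cand[, 2] > half & cand[, 2] <= nc - half
  cand <- cand[keep, , drop = FALSE]
  # deduplicate plateau maxima: keep the brighter of any pair within 2 px
  if (nrow(cand) > 1) {
    o <- order(f[cand], decreasing = TRUE)
    cand <- cand[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))[-1]) {
      d2 <- (cand[1:(i - 1), 1] - cand[i, 1])^2 + (cand[1:(i - 1), 2] - cand[i, 2])^2
      if (any(keep[1:(i - 1)] & d2 <= 4)) keep[i] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  cand
}

#' Fit a sub-pixel 2D Gaussian to a candidate spot
#'
#' Least-squares fit of `b + A * exp(-((x-x0)^2+(y-y0)^2) / (2 s^2))` over a
#' square window around the candidate. Photon count is `N = 2 pi A s^2` (s in
#' px). The fit is rejected (returns NULL) on non-convergence, non-positive
#' amplitude, or a fitted sd outside `[0.5, 3]` times the PSF prior.
#'
#' @param frame_image photon-count matrix.
#' @param candidate `c(row, col)` 1-based pixel indices.
#' @param pixel_size nm/px.
#' @param psf_sigma PSF sd prior in nm (initializes and bounds the fit).
#' @param window odd window edge in px (default 7).
#' @return a one-row data.frame (x, y, sigma nm; intensity photons; offset,
#'   bkgstd photons/px) or NULL if the fit is rejected.
#' @export
fit_gaussian <- function(frame_image, candidate, pixel_size, psf_sigma = 150,
                         window = 7) {
  half <- window %/% 2
  r0 <- candidate[1]; c0 <- candidate[2]
  if (r0 - half < 1 || r0 + half > nrow(frame_image) ||
      c0 - half < 1 || c0 + half > ncol(frame_image)) {
    stop_invalid("fit window extends outside the frame")
  }
  z <- frame_image[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
  # pixel-center coordinates in px units, window-local
  xs <- (c0 - half):(c0 + half) - 0.5
  ys <- (r0 - half):(r0 + half) - 0.5
  # as.vector(z) is column-major: y (rows) varies fastest
  d <- data.frame(x = rep(xs, each = window), y = rep(ys, times = window),
                  z = as.vector(z))
  s_px <- psf_sigma / pixel_size
  st <- list(b = min(d$z), A = max(d$z) - min(d$z), x0 = c0 - 0.5, y0 = r0 - 0.5, s = s_px)
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)),
                      data = d, start = st,
                      lower = c(b = 0, A = 0, x0 = min(xs), y0 = min(ys), s = 0.2 * s_px),
                      upper = c(b = Inf, A = Inf, x0 = max(xs), y0 = max(ys), s = 5 * s_px),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- as.list(stats::coef(fit))
  if (p$A <= 0 || p$s < 0.5 * s_px || p$s > 3 * s_px) return(NULL)
  n_photons <- 2 * pi * p$A * p$s^2
  if (!is.finite(n_photons) || n_photons < 1) return(NULL)
  data.frame(x = p$x0 * pixel_size, y = p$y0 * pixel_size,
             sigma = p$s * pixel_size, intensity = n_photons,
             offset = p$b, bkgstd = stats::sd(stats::resid(fit)))
}

#' Thompson-style localization precision
#'
#' Lateral precision of a least-squares Gaussian fit:
#' `sigma_loc = sqrt((s^2 + a^2/12)/N + 8 pi s^4 b^2 / (a^2 N^2))` with
#' `s` the fitted PSF sd (nm), `a` the pixel size (nm), `N` the photon count
#' and `b` the background sd per pixel.
#'
#' @param sigma fitted PSF sd, nm (vectorized).
#' @param intensity photon count N (> 0).
#' @param bkgstd background sd per pixel, photons.
#' @param pixel_size pixel size a, nm.
#' @return precision in nm.
#' @export
estimate_precision <- function(sigma, intensity, bkgstd, pixel_size) {
  if (any(intensity <= 0)) stop_invalid("photon count must be > 0")
  sqrt((sigma^2 + pixel_size^2 / 12) / intensity +
       8 * pi * sigma^4 * bkgstd^2 / (pixel_size^2 * intensity^2))
}

#' Localize a full frame stack
#'
#' Runs [detect_spots()] and [fit_gaussian()] on every frame, attaches the
#' precision of [estimate_precision()], and drops duplicate fits that land
#' within one fitted sigma of a brighter fit in the same frame.
#'
#' @param stack a `frame_stack` (or array with `pixel_size`/`exposure`
#'   attributes).
#' @param pixel_size,exposure acquisition metadata; default from the stack.
#' @param psf_sigma PSF sd prior, nm.
#' @param peak_threshold,window,band_sigmas passed to the detector/fitter.
#' @return a `loc_table` sorted by frame.
#' @export
localize_stack <- function(stack, pixel_size = attr(stack, "pixel_size"),
                           exposure = attr(stack, "exposure"),
                           psf_sigma = 150, peak_threshold = 4, window = 7,
                           band_sigmas = c(psf_sigma, 2 * psf_sigma)) {
  nf <- dim(stack)[3]
  fov <- c(dim(stack)[2], dim(stack)[1]) * pixel_size
  out <- vector("list", nf)
  for (k in seq_len(nf)) {
    frame <- stack[, , k]
    cand <- detect_spots(frame, pixel_size, band_sigmas, peak_threshold, window)
    if (!nrow(cand)) next
    fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      fit_gaussian(frame, cand[i, ], pixel_size, psf_sigma, window)
    }))
    if (is.null(fits) || !nrow(fits)) next
    # in-frame dedup: keep the brighter of two fits within one fitted sigma
    o <- order(fits$intensity, decreasing = TRUE)
    fits <- fits[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(fits))
    for (i in seq_len(nrow(fits))[-1]) {
      d2 <- (fits$x[1:(i - 1)] - fits$x[i])^2 + (fits$y[1:(i - 1)] - fits$y[i])^2
      if (any(keep[1:(i - 1)] & d2 <= fits$sigma[i]^2)) keep[i] <- FALSE
    }
    fits <- fits[keep, , drop = FALSE]
    # clip: a fit never leaves the fov
    fits <- fits[fits$x >= 0 & fits$x <= fov[1] & fits$y >= 0 & fits$y <= fov[2], ,
                 drop = FALSE]
    if (!nrow(fits)) next
    fits$frame <- k
    out[[k]] <- fits
  }
  rec <- do.call(rbind, out)
  if (is.null(rec)) {
    rec <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      sigma = numeric(0), intensity = numeric(0),
                      offset = numeric(0), bkgstd = numeric(0),
                      uncertainty = numeric(0))
  } else {
    rec$uncertainty <- estimate_precision(rec$sigma, rec$intensity, rec$bkgstd,
                                          pixel_size)
  }
  loc_table(rec, pixel_size = pixel_size, exposure = exposure, fov = fov)
}

#' Filter localizations by precision
#'
#' Retains records whose uncertainty is strictly below the threshold
#' (default 30 nm). Order and metadata are preserved; idempotent.
#'
#' @param table a `loc_table`.
#' @param max_uncertainty precision threshold in nm.
#' @return filtered `loc_table`.
#' @export
filter_precision <- function(table, max_uncertainty = 30) {
  if (max_uncertainty <= 0) stop_invalid("max_uncertainty must be > 0")
  subset_loc_table(table, table$uncertainty < max_uncertainty)
}
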
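## frc: Fourier ring correlation resolution estimation.
##
## The localization set is split at random into two statistically independent
## halves, each half is rendered as a count histogram, and the correlation of
## the two discrete Fourier transforms is averaged over rings of constant
## spatial frequency. The image resolution is the inverse of the frequency at
## which the (lightly smoothed) ring correlation first drops below a fixed
## threshold (1/7 by convention).

next_pow2 <- function(n) 2L^as.integer(ceiling(log2(max(n, 2L))))

# ring index (0-based integer radius in FFT pixels) for an n x n transform
ring_index <- function(n) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # fftfreq * n
  fx <- matrix(rep(f, each = n), n, n)
  fy <- matrix(rep(f, times = n), n, n)
  matrix(as.integer(round(sqrt(fx^2 + fy^2))), n, n)
}

#' Fourier ring correlation of two images
#'
#' Zero-pads both images to a common power-of-two square, transforms, and
#' correlates over integer-radius frequency rings:
#' `FRC(q) = Re sum(F1 conj(F2)) / sqrt(sum|F1|^2 sum|F2|^2)`.
#'
#' @param img1,img2 numeric matrices of equal orientation (the two half-data
#'   renderings; any common pixel grid).
#' @param render_bin nm per pixel of the images (sets the frequency scale).
#' @return an `frc_curve`: data.frame columns `freq` (1/nm, rings 1..Nyquist)
#'   and `frc`; attributes `render_bin`, `fft_size`.
#' @export
frc_from_images <- function(img1, img2, render_bin) {
  d <- c(max(nrow(img1), nrow(img2)), max(ncol(img1), ncol(img2)))
  n <- next_pow2(max(d))
  pad <- function(m) {
    out <- matrix(0, n, n)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  f1 <- stats::fft(pad(img1))
  f2 <- stats::fft(pad(img2))
  ring <- ring_index(n)
  nb <- n %/% 2 + 1L                      # rings 0 .. Nyquist
  sel <- ring < nb
  rid <- ring[sel] + 1L
  num <- vapply(split(Re(f1[sel] * Conj(f2[sel])), rid), sum, 0)
  d1 <- vapply(split(abs(f1[sel])^2, rid), sum, 0)
  d2 <- vapply(split(abs(f2[sel])^2, rid), sum, 0)
  den <- sqrt(d1 * d2)
  frc <- ifelse(den > 0, num / den, 0)
  r <- as.integer(names(num))             # 1-based ring id = radius + 1
  keep <- r >= 2L                         # drop the DC ring
  structure(data.frame(freq = (r[keep] - 1L) / (n * render_bin), frc = frc[keep]),
            render_bin = render_bin, fft_size = n,
            class = c("frc_curve", "data.frame"))
}

#' FRC curve of a localization table via a random half split
#'
#' @param table a `loc_table` with at least 2 records.
#' @param render_bin nm/px for the half-data histograms (default 10).
#' @param split_seed seed for the random equal split.
#' @param fov field of view, nm; default from metadata.
#' @return an `frc_curve` (see [frc_from_images()]); also carries `n_loc`.
#' @export
frc_curve <- function(table, render_bin = 10, split_seed = 1, fov = loc_fov(table)) {
  n <- nrow(table)
  if (n < 2) stop_insufficient("need at least 2 localizations for FRC")
  half <- with_seed(substream_seed(split_seed, "frc-split"),
                    sample.int(n, n %/% 2))
  img1 <- render_histogram(subset_loc_table(table, half), render_bin, fov = fov)
  img2 <- render_histogram(subset_loc_table(table, setdiff(seq_len(n), half)),
                           render_bin, fov = fov)
  out <- frc_from_images(img1, img2, render_bin)
  attr(out, "n_loc") <- n
  out
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("FRC curve: %d rings to Nyquist %.4g 1/nm (render bin %g nm)\n",
              nrow(x), max(x$freq), attr(x, "render_bin")))
  invisible(x)
}

#' @export
plot.frc_curve <- function(x, threshold = 1 / 7, ...) {
  graphics::plot(x$freq, x$frc, type = "l", xlab = "spatial frequency (1/nm)",
                 ylab = "FRC", ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Threshold-crossing resolution of an FRC curve
#'
#' The curve is smoothed with a centered moving average over
#' `smooth_window` rings (default 3) to suppress single-ring noise, then the
#' resolution is `1/q*` with `q*` the first ring frequency at which the
#' smoothed curve falls below `threshold`. Returns `NA` (flagged, not an
#' error) when the curve never crosses below the Nyquist frequency.
#'
#' @param curve an `frc_curve`.
#' @param threshold fixed FRC threshold (default 1/7).
#' @param smooth_window moving-average width in rings (odd; 1 = no smoothing).
#' @return resolution in nm, or `NA_real_` when undefined.
#' @export
frc_resolution <- function(curve, threshold = 1 / 7, smooth_window = 3) {
  v <- curve$frc
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(v, k, sides = 2)
    # centered average shrinks at the ends; fall back to raw values there
    v <- ifelse(is.na(sm), v, as.numeric(sm))
  }
  i <- which(v < threshold)
  if (!length(i)) return(NA_real_)
  1 / curve$freq[min(i)]
}

#' Resolution as a function of integration time
#'
#' For each requested integration time, draws `n_reps` random frame subsets
#' whose total exposure equals that time (frames sampled without
#' replacement), computes the FRC resolution of each subset, and reports the
#' mean and sd across replicates.
#'
#' @param table a `loc_table`.
#' @param times integration times in seconds (each at most the acquisition
#'   length).
#' @param n_reps replicates per time (default 3).
#' @param seed RNG seed for frame sampling and the FRC splits.
#' @param render_bin nm/px.
#' @param threshold,smooth_window passed to [frc_resolution()].
#' @param contiguous if TRUE, sample a random contiguous frame block instead
#'   of scattered frames.
#' @return a `resolution_series`: data.frame with `time`, `mean_resolution`,
#'   `sd_resolution`, `n_reps`, `n_loc_mean`.
#' @export
resolution_vs_integration <- function(table, times, n_reps = 3, seed = 1,
                                      render_bin = 10, threshold = 1 / 7,
                                      smooth_window = 3, contiguous = FALSE) {
  exposure <- loc_exposure(table)
  n_frames_total <- max(table$frame)
  res <- matrix(NA_real_, length(times), n_reps)
  nloc <- matrix(NA_real_, length(times), n_reps)
  for (ti in seq_along(times)) {
    n_sub <- as.integer(round(times[ti] / exposure))
    if (n_sub < 1 || n_sub > n_frames_total) {
      stop_invalid("integration time ", times[ti], " s outside the acquisition")
    }
    for (r in seq_len(n_reps)) {
      sub_seed <- substream_seed(seed, sprintf("frc-sub-%d-%d", ti, r))
      frames <- with_seed(sub_seed, {
        if (contiguous) {
          s <- sample.int(n_frames_total - n_sub + 1L, 1L)
          s:(s + n_sub - 1L)
        } else {
          sample.int(n_frames_total, n_sub)
        }
      })
      sub <- subset_loc_table(table, table$frame %in% frames)
      if (nrow(sub) < 2) next
      cv <- frc_curve(sub, render_bin, split_seed = sub_seed)
      res[ti, r] <- frc_resolution(cv, threshold, smooth_window)
      nloc[ti, r] <- nrow(sub)
    }
  }
  structure(data.frame(time = times,
                       mean_resolution = rowMeans(res, na.rm = TRUE),
                       sd_resolution = apply(res, 1, stats::sd, na.rm = TRUE),
                       n_reps = n_reps,
                       n_loc_mean = rowMeans(nloc, na.rm = TRUE)),
            replicates = res,
            class = c("resolution_series", "data.frame"))
}
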
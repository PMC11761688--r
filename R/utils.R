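#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed and a label
#'
#' All stochastic operations in the package draw their seeds from one master
#' seed through named substreams, so that e.g. the binding-kinetics draws and
#' the camera-noise draws of one simulation are decoupled but jointly
#' reproducible.
#'
#' @param seed master seed (single integer).
#' @param name substream label (character scalar).
#' @return an integer seed in [0, 2^31 - 2].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (v in utf8ToInt(name)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("paintkit_invalid_parameter", "error")))
}

stop_insufficient <- function(...) {
  stop(errorCondition(paste0(...), class = c("paintkit_insufficient_data", "error")))
}

# coerce a points argument (matrix / data.frame with x,y) to an n x 2 matrix
as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x", "y") %in% names(points))) {
      points <- cbind(points$x, points$y)
    } else {
      points <- as.matrix(points[, 1:2])
    }
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop_invalid("points must have two columns (x, y)")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  points
}
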
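#' Construct a localization table
#'
#' The central data container of the pipeline: one row per localization with
#' the ThunderSTORM-style fields, plus acquisition metadata carried as
#' attributes so that downstream stages (rendering, FRC, linking) know the
#' pixel size, exposure time and field of view without re-asking.
#'
#' @param records data.frame with (at least) columns `frame` (1-based),
#'   `x`, `y` (nm), `uncertainty` (nm). Optional columns `sigma` (nm, fitted
#'   PSF sd), `intensity` (photons), `offset` (photons/px), `bkgstd`
#'   (photons/px) are kept; missing ones are filled with `NA`.
#' @param pixel_size camera pixel size in nm (NA for direct-mode simulated
#'   tables that never touched a camera).
#' @param exposure exposure time per frame in seconds.
#' @param fov field of view `c(width, height)` in nm.
#' @return object of class `loc_table` (a data.frame sorted by frame, with
#'   a `time` column equal to `(frame - 1) * exposure`).
#' @export
loc_table <- function(records, pixel_size = NA_real_, exposure, fov) {
  records <- as.data.frame(records)
  need <- c("frame", "x", "y", "uncertainty")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_invalid("missing localization columns: ", paste(miss, collapse = ", "))
  for (col in c("sigma", "intensity", "offset", "bkgstd")) {
    if (is.null(records[[col]])) records[[col]] <- rep(NA_real_, nrow(records))
  }
  if (nrow(records)) {
    if (any(records$frame < 1)) stop_invalid("frame indices must be >= 1")
    if (any(records$uncertainty <= 0, na.rm = TRUE)) stop_invalid("uncertainties must be > 0")
  }
  ord <- order(records$frame)                      # stable: keeps detection order
  records <- records[ord, , drop = FALSE]
  records$time <- (records$frame - 1) * exposure
  records <- records[, c("frame", "x", "y", "sigma", "intensity",
                         "offset", "bkgstd", "uncertainty", "time")]
  rownames(records) <- NULL
  structure(records,
            pixel_size = pixel_size, exposure = exposure, fov = fov,
            class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("Localization table: %d records, exposure %g s, fov %g x %g nm\n",
              nrow(x), attr(x, "exposure"), attr(x, "fov")[1], attr(x, "fov")[2]))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# rebuild a loc_table after row subsetting, preserving metadata
subset_loc_table <- function(table, keep) {
  structure(`rownames<-`(as.data.frame(table)[keep, , drop = FALSE], NULL),
            pixel_size = attr(table, "pixel_size"),
            exposure = attr(table, "exposure"),
            fov = attr(table, "fov"),
            class = c("loc_table", "data.frame"))
}

loc_exposure <- function(table) {
  e <- attr(table, "exposure")
  if (is.null(e) || !is.finite(e)) stop_invalid("localization table lacks exposure metadata")
  e
}

loc_fov <- function(table) {
  f <- attr(table, "fov")
  if (is.null(f)) stop_invalid("localization table lacks fov metadata")
  f
}
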
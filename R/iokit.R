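## iokit: file formats, configuration and the end-to-end pipeline.

ts_cols <- c(id = "id", frame = "frame", x = "x [nm]", y = "y [nm]",
             sigma = "sigma [nm]", intensity = "intensity [photon]",
             offset = "offset [photon]", bkgstd = "bkgstd [photon]",
             uncertainty = "uncertainty [nm]")

#' Read a ThunderSTORM-style localization CSV
#'
#' Comma-separated, dot-decimal, quoted headers of the form
#' `"frame","x [nm]","y [nm]",...`. The columns `frame`, `x [nm]`, `y [nm]`
#' and `uncertainty [nm]` are mandatory; the other standard columns
#' (`id`, `sigma [nm]`, `intensity [photon]`, `offset [photon]`,
#' `bkgstd [photon]`) are optional.
#'
#' @param path file path.
#' @param pixel_size,exposure,fov acquisition metadata to attach (the CSV
#'   itself carries none); fov defaults to the data extent.
#' @return a `loc_table`.
#' @export
read_localization_csv <- function(path, pixel_size = NA_real_, exposure = 0.05,
                                  fov = NULL) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- ts_cols[c("frame", "x", "y", "uncertainty")]
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(errorCondition(paste0("missing mandatory column(s): ",
                               paste(dQuote(miss, FALSE), collapse = ", ")),
                        class = c("paintkit_schema_error", "error")))
  }
  for (col in intersect(ts_cols, names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop(errorCondition(paste0("non-numeric value in column ", dQuote(col, FALSE),
                                 " at data row ", if (length(bad)) bad[1] else NA),
                          class = c("paintkit_parse_error", "error")))
    }
  }
  rec <- data.frame(frame = df[[ts_cols["frame"]]],
                    x = df[[ts_cols["x"]]], y = df[[ts_cols["y"]]],
                    uncertainty = df[[ts_cols["uncertainty"]]])
  for (nm in c("sigma", "intensity", "offset", "bkgstd")) {
    cn <- ts_cols[nm]
    if (cn %in% names(df)) rec[[nm]] <- df[[cn]]
  }
  if (is.null(fov)) {
    fov <- c(max(rec$x, 0), max(rec$y, 0))
  }
  loc_table(rec, pixel_size = pixel_size, exposure = exposure, fov = fov)
}

#' Write a localization table in the ThunderSTORM CSV dialect
#'
#' Fixed column order `"id","frame","x [nm]","y [nm]","sigma [nm]",
#' "intensity [photon]","offset [photon]","bkgstd [photon]",
#' "uncertainty [nm]"`; one row per record in table order.
#'
#' @param table a `loc_table`.
#' @param path file path.
#' @export
write_localization_csv <- function(table, path) {
  df <- data.frame(check.names = FALSE,
                   id = seq_len(nrow(table)),
                   frame = table$frame, x = table$x, y = table$y,
                   sigma = table$sigma, intensity = table$intensity,
                   offset = table$offset, bkgstd = table$bkgstd,
                   uncertainty = table$uncertainty)
  names(df) <- ts_cols
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a merged (frame-linked) table with residence columns
#'
#' The CSV dialect of [write_localization_csv()] is not applicable here; the
#' merged table is written as comma-separated with columns
#' `x [nm]`, `y [nm]`, `detections`, `first_frame`, `last_frame`,
#' `residence_s`.
#'
#' @param merged a `merged_table`.
#' @param path file path.
#' @export
write_merged_csv <- function(merged, path) {
  df <- data.frame(check.names = FALSE,
                   `x [nm]` = merged$x, `y [nm]` = merged$y,
                   detections = merged$n_frames,
                   first_frame = merged$first_frame,
                   last_frame = merged$last_frame,
                   residence_s = merged$residence)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All stage parameters with their conventional defaults: 50 ms exposure,
#' 30 nm precision threshold, 20 nm merge radius with at most 1 off-frame,
#' DBSCAN eps 0.3 um with 5 minimum localizations, local-density highlight at
#' 5x the cluster mean NN distance, FRC threshold 1/7 with 3 replicates,
#' 25 s moving window advanced in 0.5 s steps, 10 nm render bin. Unknown
#' keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    exposure = 0.05,            # s per frame
    precision_threshold = 30,   # nm, strict <
    merge_radius = 20,          # nm
    max_off_frames = 1,
    dbscan_eps = 0.3,           # um (localizations are converted nm -> um)
    dbscan_min_pts = 5,
    nn_radius_scale = 5,
    nn_highlight = 5,
    frc_threshold = 1 / 7,
    frc_n_reps = 3,
    frc_times = NULL,           # s; NULL = ladder up to the acquisition
    render_bin = 10,            # nm/px
    window = 25,                # s
    step = 0.5,                 # s
    psf_sigma = 150,            # nm
    peak_threshold = 4,
    fit_window = 7,             # px
    seed = 1
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

config_lines <- function(cfg) {
  vapply(names(cfg), function(nm) {
    sprintf("%s = %s", nm, paste(format(cfg[[nm]], digits = 15), collapse = ","))
  }, "")
}

#' Run the full analysis pipeline
#'
#' Localize (if the input is a frame stack), filter by precision, merge
#' across frames, render, estimate FRC resolution versus integration time,
#' cluster, map local density, and build the moving-window dynamics stack.
#' Every artifact is written under `out_dir` together with a plain-text
#' manifest recording the configuration, seed and per-stage counts; the same
#' config and seed give byte-identical outputs.
#'
#' @param input a `frame_stack` or a `loc_table`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list with `filtered`, `merged`, `render`,
#'   `frc_series`, `clusters`, `density`, `window_stack`, `manifest`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message("[pipeline] ", line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (inherits(input, "frame_stack")) {
    table <- stage("localize", localize_stack(
      input, psf_sigma = config$psf_sigma,
      peak_threshold = config$peak_threshold, window = config$fit_window))
    say("localize: %d localizations from %d frames", nrow(table), dim(input)[3])
  } else if (inherits(input, "loc_table")) {
    table <- input
    say("localize: skipped (localization table input, %d records)", nrow(table))
  } else {
    stop_invalid("input must be a frame_stack or a loc_table")
  }

  filtered <- stage("filter", filter_precision(table, config$precision_threshold))
  say("filter: %d of %d records below %g nm precision",
      nrow(filtered), nrow(table), config$precision_threshold)

  merged <- stage("merge", merge_localizations(
    filtered, radius = config$merge_radius, max_off_frames = config$max_off_frames,
    exposure = config$exposure))
  say("merge: %d chains from %d localizations", nrow(merged), nrow(filtered))

  render <- stage("render", render_histogram(filtered, config$render_bin))
  say("render: %d x %d px at %g nm/px, mass %d",
      nrow(render), ncol(render), config$render_bin, sum(render))

  duration <- if (nrow(filtered)) max(filtered$time) + config$exposure else 0
  times <- config$frc_times
  if (is.null(times)) {
    times <- unique(pmin(c(duration / 4, duration / 2, duration), duration))
  }
  frc_series <- stage("frc", resolution_vs_integration(
    filtered, times = times, n_reps = config$frc_n_reps, seed = config$seed,
    render_bin = config$render_bin, threshold = config$frc_threshold))
  say("frc: resolution %s nm at times %s s",
      paste(round(frc_series$mean_resolution, 1), collapse = "/"),
      paste(times, collapse = "/"))

  pts_um <- cbind(x = filtered$x, y = filtered$y) / 1000
  labels <- stage("cluster", dbscan_cluster(pts_um, eps = config$dbscan_eps,
                                            min_pts = config$dbscan_min_pts))
  clusters <- stage("cluster", cluster_metrics(pts_um, labels))
  say("cluster: %d clusters, %.2f%% clustered",
      clusters$n_clusters, 100 * clusters$fraction_clustered)

  density <- stage("density", local_density_map(pts_um, labels,
                                                radius_scale = config$nn_radius_scale))
  mask <- highlight_threshold(density, config$nn_highlight)
  say("density: %d of %d members within %gx mean NN distance",
      sum(mask, na.rm = TRUE), sum(!is.na(mask)), config$nn_highlight)

  window_stack <- if (duration >= config$window) {
    stage("dynamics", moving_window_stack(filtered, window = config$window,
                                          step = config$step,
                                          render_bin = config$render_bin,
                                          duration = duration))
  } else {
    say("dynamics: skipped (acquisition %.3g s shorter than window %g s)",
        duration, config$window)
    list()
  }
  if (length(window_stack)) {
    say("dynamics: %d windows of %g s, step %g s",
        length(window_stack), config$window, config$step)
  }

  # artifacts
  write_localization_csv(filtered, file.path(out_dir, "filtered.csv"))
  write_merged_csv(merged, file.path(out_dir, "merged.csv"))
  write_render_tiff(render, file.path(out_dir, "render.tif"))
  utils::write.table(as.data.frame(frc_series), file.path(out_dir, "frc_series.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(clusters$per_cluster, file.path(out_dir, "cluster_metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  dens_out <- cbind(as.data.frame(density), highlighted = mask)
  utils::write.table(dens_out, file.path(out_dir, "density.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (length(window_stack)) {
    write_render_tiff(window_stack, file.path(out_dir, "window_stack.tif"))
  }
  manifest <- c("paintkit pipeline manifest",
                "", "config:", paste0("  ", config_lines(config)),
                "", "stages:", paste0("  ", log_lines))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(filtered = filtered, merged = merged, render = render,
                 frc_series = frc_series, clusters = clusters,
                 density = density, highlight = mask,
                 window_stack = window_stack,
                 manifest = file.path(out_dir, "manifest.txt")))
}
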
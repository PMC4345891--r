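#' Map heat values to overlay alpha
#'
#' The shared color-intensity rule used by [render_heatmap()]: heat is
#' clipped at `clip` (when set) and mapped affinely from
#' `[scale_min, scale_max]` onto alpha `[0, 1]`, clamped. Monotone
#' non-decreasing in heat, and identical to the evaluator clip rule.
#'
#' @param heat numeric heat values (evaluator units).
#' @param scale_min,scale_max color scale limits; must differ.
#' @param clip optional ceiling applied before scaling.
#' @return alpha values in `[0, 1]` (`NA` heat stays `NA`).
#' @export
#' @examples
#' heat_alpha(c(0, 15, 30, 45), 0, 30, clip = 30)
heat_alpha <- function(heat, scale_min, scale_max, clip = NULL) {
  if (scale_min == scale_max) stopf("degenerate color scale (min == max)")
  h <- if (!is.null(clip)) pmin(heat, clip) else heat
  clamp((h - scale_min) / (scale_max - scale_min), 0, 1)
}

roi_outline <- function(roi, n_ellipse = 90L) {
  switch(roi$kind,
    rectangle = {
      p <- roi$params
      cbind(x = c(p[1], p[3], p[3], p[1]), y = c(p[2], p[2], p[4], p[4]))
    },
    ellipse = {
      p <- roi$params
      th <- seq(0, 2 * pi, length.out = n_ellipse)
      cbind(x = p[1] + p[3] * cos(th), y = p[2] + p[4] * sin(th))
    },
    polygon = roi$params)
}

# grid leaves (optionally a subset) as rectangle ROIs keyed by cell id
grid_regions <- function(grid, ids = NULL) {
  lv <- grid_leaves(grid)
  if (!is.null(ids)) lv <- lv[lv$id %in% ids, , drop = FALSE]
  rois <- lapply(seq_len(nrow(lv)), function(i)
    make_roi("rectangle", c(lv$x0[i], lv$y0[i], lv$x1[i], lv$y1[i]),
             id = lv$id[i]))
  names(rois) <- lv$id
  rois
}

#' Render a heat map over the field of view
#'
#' Draws each stimulated region over the background image, filled with a
#' single hue whose alpha follows [heat_alpha()] — regions causing larger
#' depolarization appear as hot spots. Regions with undefined heat (all
#' trials rejected) are drawn as dashed outlines with no fill. A color bar
#' in evaluator units and a JSON sidecar (region, heat, alpha, optional
#' per-region waveform file) are emitted alongside the PNG.
#'
#' @param heat_results a `"heat_result"` from [aggregate_heat()].
#' @param regions named list of [make_roi()] objects (or a `smart_grid`,
#'   whose leaves are used) covering every pattern in `heat_results`.
#' @param out_path output PNG path; the sidecar goes to `<out_path>.json`.
#' @param background background image: a matrix in `[0, 1]`, a TIFF/PNG
#'   path, or `NULL` for a blank canvas.
#' @param scale `c(min, max)` of the color scale, evaluator units.
#' @param clip presentation clip applied to heat before scaling (mV);
#'   `NULL` disables clipping.
#' @param color overlay hue.
#' @param waveform_index optional named character vector mapping pattern id
#'   to its exported waveform file, recorded in the sidecar.
#' @param width,height device size, px.
#' @return invisibly, a `"heatmap_figure"`: per-region data frame
#'   (pattern_id, heat, alpha), scale, clip, file paths.
#' @export
render_heatmap <- function(heat_results, regions, out_path,
                           background = NULL, scale = c(0, 30), clip = 30,
                           color = "#ff2a00", waveform_index = NULL,
                           width = 800, height = 800) {
  if (inherits(regions, "smart_grid")) regions <- grid_regions(regions)
  ids <- vapply(regions, `[[`, "", "id")
  names(regions) <- ids
  df <- as.data.frame(heat_results)
  missing <- setdiff(df$pattern_id, ids)
  if (length(missing))
    stopf("no region geometry for pattern(s): %s", paste(missing, collapse = ", "))
  alpha <- heat_alpha(df$heat, scale[1], scale[2], clip)

  bg <- if (is.character(background)) read_background(background) else background
  # drawing extent: background size or the union of region bounds
  if (!is.null(bg)) {
    xlim <- c(0, ncol(bg)); ylim <- c(0, nrow(bg))
  } else {
    allpts <- do.call(rbind, lapply(regions, roi_outline))
    xlim <- range(allpts[, 1]); ylim <- range(allpts[, 2])
  }

  grDevices::png(out_path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(2, 2, 2, 5))
  graphics::plot(NA, xlim = xlim, ylim = rev(ylim), asp = 1,
                 xlab = "", ylab = "", main = "heat map",
                 xaxs = "i", yaxs = "i")
  if (!is.null(bg))
    graphics::rasterImage(bg, xlim[1], ylim[2], xlim[2], ylim[1])
  for (i in seq_len(nrow(df))) {
    pts <- roi_outline(regions[[df$pattern_id[i]]])
    if (is.na(alpha[i])) {
      graphics::polygon(pts[, 1], pts[, 2], border = "grey50", lty = 2)
    } else {
      graphics::polygon(pts[, 1], pts[, 2],
                        col = grDevices::adjustcolor(color, alpha.f = alpha[i]),
                        border = "grey30", lwd = 0.5)
    }
  }
  # color bar
  units <- attr(heat_results, "units") %||% "mV"
  nramp <- 64L
  ramp <- grDevices::as.raster(matrix(
    rev(vapply(seq(0, 1, length.out = nramp),
               function(a) grDevices::adjustcolor(color, alpha.f = a), "")),
    ncol = 1))
  usr <- graphics::par("usr")
  bx0 <- usr[2] + 0.02 * diff(usr[1:2]); bx1 <- usr[2] + 0.05 * diff(usr[1:2])
  graphics::par(xpd = NA)
  graphics::rasterImage(ramp, bx0, usr[3], bx1, usr[4])
  graphics::text(bx1, usr[3], sprintf("%g", scale[2]), pos = 4, cex = 0.8)
  graphics::text(bx1, usr[4], sprintf("%g", scale[1]), pos = 4, cex = 0.8)
  graphics::text(bx1, mean(usr[3:4]), units, pos = 4, cex = 0.8)

  sidecar <- list(regions = data.frame(
                    pattern_id = df$pattern_id, heat = df$heat, alpha = alpha,
                    waveform = if (!is.null(waveform_index))
                      unname(waveform_index[df$pattern_id]) else NA,
                    stringsAsFactors = FALSE),
                  scale = scale, clip = clip, units = units,
                  image = out_path)
  jsonlite::write_json(sidecar, paste0(out_path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(structure(c(sidecar, list(png = out_path,
                                      sidecar = paste0(out_path, ".json"))),
                      class = "heatmap_figure"))
}

#' Export the waveforms behind one region's heat value
#'
#' Writes an overlay plot (thin per-trial traces, bold mean, shaded
#' stimulation window) and a CSV of time versus per-trial voltage — the
#' non-interactive equivalent of clicking a region on the heat map.
#'
#' @param epochs an `"epoch_list"`.
#' @param pattern_id which pattern's epochs to export.
#' @param path base output path: writes `<path>.png` and `<path>.csv`.
#' @param stim_window optional `c(start, end)` seconds relative to onset to
#'   shade (e.g. `c(0, exposure)`).
#' @return invisibly, `list(png, csv, n_trials)`.
#' @export
export_waveforms <- function(epochs, pattern_id, path, stim_window = NULL) {
  es <- epochs[vapply(epochs, `[[`, "", "pattern_id") == pattern_id]
  if (length(es) == 0L) stopf("no epochs for pattern '%s'", pattern_id)
  fs <- es[[1]]$sample_rate
  m <- vapply(es, `[[`, numeric(length(es[[1]]$samples)), "samples")
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  t_ms <- (seq_len(nrow(m)) - es[[1]]$onset_index - 1L) / fs * 1000
  mean_tr <- rowMeans(m)

  csv <- paste0(path, ".csv")
  out <- data.frame(time_ms = t_ms, m, mean = mean_tr)
  names(out) <- c("time_ms", sprintf("trial_%d", seq_len(ncol(m))), "mean")
  utils::write.csv(out, csv, row.names = FALSE)

  png <- paste0(path, ".png")
  grDevices::png(png, width = 700, height = 450)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::matplot(t_ms, m, type = "l", lty = 1, col = "grey60",
                    xlab = "time from onset (ms)", ylab = "Vm (mV)",
                    main = sprintf("%s (%d trials)", pattern_id, ncol(m)))
  if (!is.null(stim_window)) {
    usr <- graphics::par("usr")
    graphics::rect(stim_window[1] * 1000, usr[3], stim_window[2] * 1000,
                   usr[4], col = grDevices::adjustcolor("skyblue", 0.3),
                   border = NA)
  }
  graphics::lines(t_ms, mean_tr, col = "black", lwd = 2)
  invisible(list(png = png, csv = csv, n_trials = ncol(m)))
}

# --- experiment archive -------------------------------------------------

#' Save / load / re-analyze a complete experiment archive
#'
#' `save_archive` writes every artifact needed to reproduce an analysis —
#' recording, masks, protocol, evaluation parameters, optional results —
#' into a directory, finishing with a manifest of content hashes (written
#' last, so a partial archive is detectably incomplete). `load_archive`
#' verifies the hashes and reloads the components. `analyze_archive`
#' re-runs segmentation and aggregation purely from archive contents;
#' because the whole chain is deterministic, it reproduces the stored heat
#' values bit for bit.
#'
#' @param out_dir archive directory (created if needed).
#' @param protocol a `stim_protocol`.
#' @param masks named list of [pattern_mask()].
#' @param recording a `rig_recording`.
#' @param heat_results optional `"heat_result"` to store.
#' @param params named list of analysis parameters (evaluator, evaluator
#'   params, `pre`, `post`, rejection settings); stored as JSON and used by
#'   `analyze_archive`.
#' @return `save_archive`: invisibly, the manifest path. `load_archive`: a
#'   list with `protocol`, `masks`, `recording`, `params`, `heat_results`
#'   (if stored). `analyze_archive`: a fresh `"heat_result"`.
#' @export
save_archive <- function(out_dir, protocol, masks, recording,
                         heat_results = NULL, params = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  protocol_to_json(protocol, file.path(out_dir, "protocol.json"))
  write_masks(masks, file.path(out_dir, "masks.tif"))
  write_recording(recording, file.path(out_dir, "recording"))
  jsonlite::write_json(params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(heat_results))
    write_heat_results(heat_results, file.path(out_dir, "results"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  hashes <- as.character(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(files = files, md5 = hashes)
  # manifest written last and atomically (rename) so partial writes leave
  # no manifest behind
  tmp <- file.path(out_dir, ".manifest.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  autolog("save_archive: %s (%d files)", out_dir, length(files))
  invisible(file.path(out_dir, "manifest.json"))
}

#' @rdname save_archive
#' @param dir archive directory.
#' @export
load_archive <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stopf("no manifest in '%s' (incomplete archive?)", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  for (i in seq_along(mf$files)) {
    f <- file.path(dir, mf$files[i])
    if (!file.exists(f)) stopf("archive file missing: %s", mf$files[i])
    h <- as.character(tools::md5sum(f))
    if (!identical(h, mf$md5[i]))
      stopf("archive integrity error: hash mismatch for %s", mf$files[i])
  }
  out <- list(
    protocol = protocol_from_json(file.path(dir, "protocol.json")),
    masks = read_masks(file.path(dir, "masks.tif")),
    recording = read_recording(file.path(dir, "recording")),
    params = jsonlite::read_json(file.path(dir, "params.json"),
                                 simplifyVector = TRUE))
  if (file.exists(file.path(dir, "results.json")))
    out$heat_results <- jsonlite::read_json(file.path(dir, "results.json"),
                                            simplifyVector = TRUE)
  out
}

#' @rdname save_archive
#' @export
analyze_archive <- function(dir) {
  a <- load_archive(dir)
  p <- a$params
  epochs <- segment_epochs(a$recording, a$protocol,
                           pre = p$pre %||% 0.05, post = p$post %||% 0.5)
  aggregate_heat(epochs,
                 evaluator = p$evaluator %||% "max_depolarization",
                 params = as.list(p$evaluator_params %||% list()),
                 reject = p$reject %||% TRUE,
                 reject_params = as.list(p$reject_params %||% list()))
}

# --- experiment log -----------------------------------------------------

#' Append-only experiment log
#'
#' A plain UTF-8 text log, one timestamped entry per line
#' (`<ISO-8601> [auto|user] text`). Opening an existing file never touches
#' its content; appends are flushed to disk immediately so a crash loses at
#' most the entry being written. Protocol builders, aggregation and
#' archiving auto-log when a log is active (see `options(optomap.log = )`).
#'
#' @param path log file path; created (empty) if absent. An unwritable
#'   path errors at open time.
#' @return `log_open`: an `"experiment_log"` handle. `log_append`:
#'   the handle, invisibly.
#' @export
#' @examples
#' lg <- log_open(tempfile(fileext = ".txt"))
#' log_append(lg, "patched cell 3, Rs 12 MOhm")
log_open <- function(path) {
  if (!file.exists(path)) {
    ok <- tryCatch({ file.create(path) }, warning = function(w) FALSE)
    if (!isTRUE(ok)) stopf("cannot create log file '%s'", path)
  } else if (file.access(path, 2) != 0L) {
    stopf("log file '%s' is not writable", path)
  }
  structure(list(path = path), class = "experiment_log")
}

#' @rdname log_open
#' @param log an `"experiment_log"` (or a path).
#' @param text entry text (newlines are collapsed to spaces).
#' @param source `"user"` or `"auto"`.
#' @export
log_append <- function(log, text, source = c("user", "auto")) {
  source <- match.arg(source)
  path <- if (inherits(log, "experiment_log")) log$path else log
  line <- sprintf("%s [%s] %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
                  source, gsub("[\r\n]+", " ", text))
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)  # close() flushes to disk
  writeLines(line, con)
  invisible(if (inherits(log, "experiment_log")) log else log_open(path))
}

#' @rdname log_open
#' @export
log_read <- function(path) {
  readLines(if (inherits(path, "experiment_log")) path$path else path,
            encoding = "UTF-8")
}

# internal: auto-log to the active log (options(optomap.log = path or handle))
autolog <- function(fmt, ...) {
  lg <- getOption("optomap.log")
  if (is.null(lg)) return(invisible())
  try(log_append(lg, sprintf(fmt, ...), source = "auto"), silent = TRUE)
  invisible()
}
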
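#' Simulated cell model
#'
#' A minimal model of a channelrhodopsin-expressing neuron under patterned
#' illumination: a leaky integrator driven by a photocurrent proportional to
#' the overlap between the illuminated mask and a spatial sensitivity map,
#' with an optional stereotyped spike nonlinearity and Gaussian recording
#' noise. It is deliberately not a conductance-based model; it exists to
#' give the analysis chain a ground-truth signal generator.
#'
#' Membrane dynamics (spiking disabled):
#' `dV/dt = (v_rest - V)/tau_m + gain * overlap(mask)`, with
#' `overlap = sum(sensitivity[mask ON]) / sum(sensitivity)` so that
#' full-field illumination drives at exactly `gain` (mV/ms). The
#' steady-state depolarization under constant drive is
#' `tau_m * gain * overlap`.
#'
#' @param v_rest resting membrane potential, mV.
#' @param tau_m membrane time constant, ms (> 0).
#' @param sensitivity nonnegative matrix over DMD pixels (photocurrent
#'   density; arbitrary units, normalized internally).
#' @param gain drive at full-field illumination, mV/ms.
#' @param spike_threshold spike threshold, mV, or `NULL` to disable spiking.
#' @param spike_amp spike waveform amplitude above threshold-crossing
#'   voltage, mV.
#' @param spike_dur spike waveform duration (triangular rise + fall), ms.
#' @param refractory post-spike clamp to `v_rest`, ms.
#' @param noise_sd Gaussian recording noise SD, mV (>= 0).
#' @return object of class `"cell_model"`.
#' @export
cell_model <- function(v_rest = -65, tau_m = 20, sensitivity, gain = 3,
                       spike_threshold = NULL, spike_amp = 100,
                       spike_dur = 2, refractory = 5, noise_sd = 0) {
  if (tau_m <= 0) stopf("tau_m must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is.matrix(sensitivity) || any(sensitivity < 0))
    stopf("sensitivity must be a nonnegative matrix")
  if (sum(sensitivity) <= 0) stopf("sensitivity map is zero everywhere")
  structure(list(v_rest = v_rest, tau_m = tau_m, sensitivity = sensitivity,
                 gain = gain, spike_threshold = spike_threshold,
                 spike_amp = spike_amp, spike_dur = spike_dur,
                 refractory = refractory, noise_sd = noise_sd),
            class = "cell_model")
}

#' Build a spatial photosensitivity map
#'
#' Emulates where on the field of view the simulated cell is light-
#' sensitive: `"gaussian_blob"` for a soma-like hotspot, `"dendrite_path"`
#' for a ridge of sensitivity along a polyline (a dendritic branch).
#'
#' @param kind `"gaussian_blob"` or `"dendrite_path"`.
#' @param params for `gaussian_blob`: `list(center = c(x, y), sigma,
#'   amplitude = 1)` (px; `sigma = 0` degenerates to a single pixel). For
#'   `dendrite_path`: `list(vertices = n x 2 matrix, width, amplitude = 1)`.
#' @param dmd_shape `c(rows, cols)`.
#' @param seed unused placeholder for randomized map kinds; kept for a
#'   stable call signature.
#' @return nonnegative matrix of shape `dmd_shape`.
#' @export
#' @examples
#' s <- make_sensitivity_map("gaussian_blob",
#'                           list(center = c(50, 50), sigma = 5), c(100, 100))
make_sensitivity_map <- function(kind = c("gaussian_blob", "dendrite_path"),
                                 params, dmd_shape, seed = NULL) {
  kind <- match.arg(kind)
  nr <- dmd_shape[1]; nc <- dmd_shape[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  amp <- params$amplitude %||% 1
  if (amp <= 0) stopf("amplitude must be > 0")
  if (kind == "gaussian_blob") {
    sigma <- params$sigma
    if (is.null(sigma) || sigma < 0) stopf("gaussian_blob needs sigma >= 0")
    d2 <- (cx - params$center[1])^2 + (cy - params$center[2])^2
    if (sigma < .Machine$double.eps^0.5) {
      g <- numeric(length(d2)); g[which.min(d2)] <- amp
    } else {
      g <- amp * exp(-d2 / (2 * sigma^2))
      g[g < amp * 1e-12] <- 0
    }
  } else {
    v <- as.matrix(params$vertices)
    w <- params$width
    if (is.null(w) || w <= 0) stopf("dendrite_path needs width > 0")
    if (nrow(v) < 2L) stopf("dendrite_path needs >= 2 vertices")
    d2 <- rep(Inf, length(cx))
    for (i in seq_len(nrow(v) - 1L)) {
      d2 <- pmin(d2, dist2_point_segment(cx, cy, v[i, 1], v[i, 2],
                                         v[i + 1L, 1], v[i + 1L, 2]))
    }
    g <- amp * exp(-d2 / (2 * w^2))
    g[g < amp * 1e-12] <- 0
  }
  m <- matrix(g, nrow = nr, ncol = nc)
  if (sum(m) <= 0) stopf("sensitivity map is zero everywhere")
  m
}

# squared distance from points to a segment
dist2_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px))
       else clamp(((px - x1) * dx + (py - y1) * dy) / len2, 0, 1)
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

#' Simulate the rig recording for a protocol
#'
#' Produces what the acquisition chain would record: a membrane-voltage
#' channel (mV) and a DMD output-trigger channel (V). Voltage follows the
#' leaky-integrator model of [cell_model()], Euler-integrated at the sample
#' rate; the drive at each sample is the summed normalized mask/sensitivity
#' overlap of all concurrently active exposures. When spiking is enabled, a
#' threshold crossing inserts a triangular spike waveform followed by a
#' refractory clamp to rest. The trigger channel carries a 5 V square pulse
#' starting at each event's trigger time and lasting
#' `min(5 ms, exposure)`. Gaussian recording noise (seeded) is added to the
#' voltage channel.
#'
#' @param protocol a `stim_protocol`; every `pattern_id` must have a mask.
#' @param masks named list of [pattern_mask()] objects (names or `$id`
#'   matching the protocol's pattern ids).
#' @param cell a [cell_model()] whose sensitivity matches the mask shape.
#' @param sample_rate sampling rate, Hz (>= 1000).
#' @param seed RNG seed for the recording noise.
#' @param duration total duration, seconds; default covers the last
#'   exposure plus `padding`.
#' @param padding tail after the last exposure when `duration` is `NULL`,
#'   seconds.
#' @return object of class `"rig_recording"`: `sample_rate`, `duration`,
#'   `channels$voltage` (mV), `channels$trigger` (V), and provenance
#'   metadata (seed, protocol).
#' @export
simulate_recording <- function(protocol, masks, cell, sample_rate = 10000,
                               seed = NULL, duration = NULL, padding = 0.5) {
  if (sample_rate < 1000) stopf("sample_rate must be >= 1 kHz")
  ids <- vapply(masks, `[[`, "", "id")
  if (is.null(names(masks)) || any(!nzchar(names(masks)))) names(masks) <- ids
  ev <- protocol$events
  missing <- setdiff(unique(ev$pattern_id), names(masks))
  if (length(missing))
    stopf("no mask for pattern(s): %s", paste(missing, collapse = ", "))
  total_sens <- sum(cell$sensitivity)
  dt <- 1000 / sample_rate                      # ms per sample
  duration <- duration %||% (max(ev$onset_time + ev$exposure) + padding)
  n <- round(duration * sample_rate)
  if (any(ev$onset_time + ev$exposure > duration + 1e-12))
    stopf("exposure extends past the recording duration")

  drive <- numeric(n)                           # mV/ms
  trig <- numeric(n)
  for (k in seq_len(nrow(ev))) {
    m <- masks[[ev$pattern_id[k]]]
    if (!identical(dim(m$grid), dim(cell$sensitivity)))
      stopf("mask '%s' shape does not match the sensitivity map", m$id)
    ov <- sum(cell$sensitivity[m$grid]) / total_sens
    i0 <- round(ev$onset_time[k] * sample_rate)
    i1 <- round((ev$onset_time[k] + ev$exposure[k]) * sample_rate)
    drive[(i0 + 1L):i1] <- drive[(i0 + 1L):i1] + cell$gain * ov
    t0 <- round(ev$trigger_time[k] * sample_rate)
    t1 <- round((ev$trigger_time[k] + min(0.005, ev$exposure[k])) * sample_rate)
    trig[(t0 + 1L):t1] <- 5
  }

  v <- integrate_membrane(drive, cell, dt)
  if (cell$noise_sd > 0) {
    v <- with_seed(seed, v + stats::rnorm(n, 0, cell$noise_sd))
  }
  structure(list(sample_rate = sample_rate, duration = duration,
                 channels = list(voltage = as.numeric(v), trigger = trig),
                 meta = list(seed = seed, mode = protocol$mode,
                             n_events = nrow(ev), protocol = protocol)),
            class = "rig_recording")
}

# Euler integration via a first-order recursive filter; spike insertion is
# handled in chunks (few spikes expected, each chunk stays vectorized).
integrate_membrane <- function(drive, cell, dt) {
  a <- 1 - dt / cell$tau_m
  if (a <= 0) stopf("sample rate too low for tau_m (Euler unstable)")
  b <- dt * (cell$v_rest / cell$tau_m + drive)
  n <- length(drive)
  run <- function(bseg, init)
    as.numeric(stats::filter(bseg, a, method = "recursive", init = init))
  if (is.null(cell$spike_threshold)) return(run(b, cell$v_rest))

  v <- numeric(n)
  k <- 1L
  init <- cell$v_rest
  half_n <- max(1L, round(cell$spike_dur / 2 / dt))
  ref_n <- max(0L, round(cell$refractory / dt))
  while (k <= n) {
    seg <- run(b[k:n], init)
    cross <- which(seg >= cell$spike_threshold)[1]
    if (is.na(cross)) { v[k:n] <- seg; break }
    kc <- k + cross - 1L
    v[k:kc] <- seg[seq_len(cross)]
    peak <- v[kc] + cell$spike_amp
    up <- v[kc] + (peak - v[kc]) * seq_len(half_n) / half_n
    down <- peak + (cell$v_rest - peak) * seq_len(half_n) / half_n
    wf <- c(up, down, rep(cell$v_rest, ref_n))
    idx <- kc + seq_along(wf)
    idx <- idx[idx <= n]
    v[idx] <- wf[seq_along(idx)]
    k <- kc + length(wf) + 1L
    init <- cell$v_rest
  }
  v
}

#' @export
print.rig_recording <- function(x, ...) {
  cat(sprintf("<rig_recording> %.3f s @ %g Hz, %d events (%s)\n",
              x$duration, x$sample_rate, x$meta$n_events %||% NA,
              x$meta$mode %||% "?"))
  invisible(x)
}

#' Write / read a recording archive
#'
#' The archive is a trace table (`<path>.csv`: voltage mV, trigger V) plus a
#' JSON attribute sidecar (`<path>.json`: sample rate, duration, seed, and
#' the full protocol for provenance).
#'
#' @param recording a `rig_recording`.
#' @param path base path (no extension).
#' @return `write_recording` invisibly returns the two file paths;
#'   `read_recording` the reconstructed recording.
#' @export
write_recording <- function(recording, path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  # full %.17g precision so reloading reproduces the doubles bit for bit
  utils::write.csv(data.frame(
    voltage = sprintf("%.17g", recording$channels$voltage),
    trigger = sprintf("%.17g", recording$channels$trigger),
    stringsAsFactors = FALSE), csv, row.names = FALSE, quote = FALSE)
  meta <- recording$meta
  if (!is.null(meta$protocol)) meta$protocol <- unclass(meta$protocol)
  jsonlite::write_json(list(sample_rate = recording$sample_rate,
                            duration = recording$duration, meta = meta),
                       json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(c(csv = csv, json = json))
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  tr <- utils::read.csv(paste0(path, ".csv"))
  at <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta <- at$meta
  if (!is.null(meta$protocol)) {
    pr <- meta$protocol
    meta$protocol <- new_protocol(pr$mode,
                                  as.data.frame(pr$events, stringsAsFactors = FALSE),
                                  pr$inter_stimulus_interval, pr$trig_delay,
                                  pr$repeats, isTRUE(pr$randomize), pr$seed,
                                  pr$exposure, paired_latency = pr$paired_latency,
                                  metadata = lapply(pr$metadata, unlist))
  }
  structure(list(sample_rate = at$sample_rate, duration = at$duration,
                 channels = list(voltage = tr$voltage, trigger = tr$trigger),
                 meta = meta),
            class = "rig_recording")
}
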
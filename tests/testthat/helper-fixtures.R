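# In-code fixtures shared across the suite.

# A bare synthetic epoch from a sample vector (no recording needed).
make_epoch <- function(samples, onset_index, sample_rate = 1000,
                       pattern_id = "p", condition = pattern_id, trial = 1) {
  structure(list(pattern_id = pattern_id, condition = condition,
                 trial = trial, samples = as.numeric(samples),
                 onset_index = as.integer(onset_index),
                 sample_rate = sample_rate),
            class = "stim_epoch")
}

# Epoch with a flat baseline and a saturating-exponential response
# v(t) = base + amp * (1 - exp(-t / tau)); times in seconds, tau in ms.
make_exp_epoch <- function(base = -65, amp = 30, tau_ms = 20,
                           pre = 0.05, post = 0.5, sample_rate = 10000) {
  pre_n <- round(pre * sample_rate)
  post_n <- round(post * sample_rate)
  t_ms <- (seq_len(post_n) - 1) / sample_rate * 1000
  samples <- c(rep(base, pre_n), base + amp * (1 - exp(-t_ms / tau_ms)))
  make_epoch(samples, pre_n, sample_rate)
}

# Small all-ON mask over a given DMD shape.
full_mask <- function(id, dmd_shape) {
  pattern_mask(id, matrix(TRUE, dmd_shape[1], dmd_shape[2]))
}

# Mask that switches ON a pixel-index subset (column-major indices).
index_mask <- function(id, dmd_shape, idx) {
  g <- matrix(FALSE, dmd_shape[1], dmd_shape[2])
  g[idx] <- TRUE
  pattern_mask(id, g)
}

# Uniform sensitivity map (every pixel equally photoactive).
uniform_sens <- function(dmd_shape) matrix(1, dmd_shape[1], dmd_shape[2])

# Exhaustive rasterization oracle: plain membership formulas evaluated at
# every pixel center (identity camera<->DMD mapping), independent of the
# package's inverse-affine path. Polygons go through mgcv::in.out, an
# independent even-odd implementation.
oracle_mask <- function(roi, dmd_shape) {
  nr <- dmd_shape[1]; nc <- dmd_shape[2]
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  p <- roi$params
  on <- switch(roi$kind,
    rectangle = cx >= p[1] & cx <= p[3] & cy >= p[2] & cy <= p[4],
    ellipse = ((cx - p[1]) / p[3])^2 + ((cy - p[2]) / p[4])^2 <= 1,
    polygon = mgcv::in.out(rbind(p, p[1, ]), cbind(cx, cy)))
  matrix(on, nr, nc)
}

# Random ROI over a given field, any kind.
random_roi <- function(kind, shape) {
  switch(kind,
    rectangle = {
      x <- sort(stats::runif(2, -5, shape[2] + 5))
      y <- sort(stats::runif(2, -5, shape[1] + 5))
      make_roi("rectangle", c(x[1], y[1], x[2] + 0.1, y[2] + 0.1))
    },
    ellipse = make_roi("ellipse", c(stats::runif(1, 0, shape[2]),
                                    stats::runif(1, 0, shape[1]),
                                    stats::runif(1, 0.5, shape[2] / 3),
                                    stats::runif(1, 0.5, shape[1] / 3))),
    polygon = make_roi("polygon", random_star_polygon(
      c(stats::runif(1, 5, shape[2] - 5), stats::runif(1, 5, shape[1] - 5)),
      1, min(shape) / 3, n = sample(3:9, 1))))
}

# One stimulus-response mapping run for the parameter-recovery suite:
# gaussian-blob cell, 9x9 grid battery, returns TRUE when the hottest cell
# contains the blob center.
recovery_run <- function(seed) {
  dmd <- c(72, 72)
  g <- grid_create(c(0, 0, 72, 72), 9, 9)
  lv <- grid_leaves(g)
  masks <- grid_export(g, lv$id, dmd_shape = dmd)
  center <- with_seed_local(seed, stats::runif(2, 4, 68))
  sens <- make_sensitivity_map("gaussian_blob",
                               list(center = center, sigma = 3), dmd)
  cm <- cell_model(v_rest = -65, tau_m = 20, sensitivity = sens, gain = 3,
                   noise_sd = 1)
  p <- build_autostim(lv$id, exposure = 0.02, isi = 0.1, repeats = 3,
                      randomize = TRUE, seed = seed)
  rec <- simulate_recording(p, masks, cm, sample_rate = 2000,
                            seed = seed + 1L, padding = 0.1)
  ep <- segment_epochs(rec, p, pre = 0.03, post = 0.05)
  h <- aggregate_heat(ep, params = list(response_window = 0.03,
                                        baseline_window = 0.03))
  best <- lv[lv$id == h$pattern_id[which.max(h$heat)], ]
  center[1] >= best$x0 && center[1] < best$x1 &&
    center[2] >= best$y0 && center[2] < best$y1
}

# seed-scoped RNG draw that restores the caller's stream
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Random simple (star-shaped) polygon around a center.
random_star_polygon <- function(center, rmin, rmax, n = 7) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
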
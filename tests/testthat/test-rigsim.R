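test_that("an unstimulated noiseless cell sits at rest", {
  dmd <- c(10, 10)
  p <- build_autostim("m", exposure = 0.01, isi = 0.05, start = 0.05)
  masks <- list(m = index_mask("m", dmd, integer()))  # all-off mask
  cm <- cell_model(sensitivity = uniform_sens(dmd), gain = 3)
  # all-off mask -> zero drive; trace must stay at v_rest
  rec <- simulate_recording(p, masks, cm, sample_rate = 1000)
  expect_equal(rec$channels$voltage, rep(-65, length(rec$channels$voltage)))
})

test_that("peak depolarization matches the driven leaky-integrator closed form", {
  dmd <- c(20, 20)
  exposure <- 0.05
  p <- build_autostim("m", exposure = exposure, isi = 0.2, start = 0.1)
  masks <- list(m = full_mask("m", dmd))
  cm <- cell_model(v_rest = -65, tau_m = 20, sensitivity = uniform_sens(dmd),
                   gain = 2)
  rec <- simulate_recording(p, masks, cm, sample_rate = 10000)
  # analytic: V(t) = v_rest + tau*gain*(1 - exp(-t/tau)), peak at end of exposure
  peak_pred <- 20 * 2 * (1 - exp(-exposure * 1000 / 20))
  peak_obs <- max(rec$channels$voltage) - (-65)
  expect_lt(abs(peak_obs - peak_pred) / peak_pred, 0.01)
})

test_that("disjoint masks superpose linearly when spiking is off", {
  dmd <- c(16, 16)
  iA <- 1:80; iB <- 120:200
  masks <- list(A = index_mask("A", dmd, iA), B = index_mask("B", dmd, iB),
                `A+B` = index_mask("A+B", dmd, c(iA, iB)))
  cm <- cell_model(sensitivity = uniform_sens(dmd), gain = 3, tau_m = 15)
  run1 <- function(id) {
    p <- build_autostim(id, exposure = 0.02, isi = 0.1, start = 0.1)
    simulate_recording(p, masks, cm, sample_rate = 10000, duration = 0.3)
  }
  vA <- run1("A")$channels$voltage + 65
  vB <- run1("B")$channels$voltage + 65
  vAB <- run1("A+B")$channels$voltage + 65
  expect_equal(vAB, vA + vB, tolerance = 1e-8)
})

test_that("identical inputs and seed give a bit-identical recording", {
  dmd <- c(12, 12)
  p <- build_autostim(c("a", "b"), 0.02, 0.1, randomize = TRUE, seed = 4)
  masks <- list(a = index_mask("a", dmd, 1:40), b = index_mask("b", dmd, 80:120))
  cm <- cell_model(sensitivity = uniform_sens(dmd), noise_sd = 1.5)
  r1 <- simulate_recording(p, masks, cm, sample_rate = 2000, seed = 99)
  r2 <- simulate_recording(p, masks, cm, sample_rate = 2000, seed = 99)
  expect_identical(r1$channels$voltage, r2$channels$voltage)
  r3 <- simulate_recording(p, masks, cm, sample_rate = 2000, seed = 100)
  expect_false(identical(r3$channels$voltage, r1$channels$voltage))
})

test_that("the trigger channel carries one pulse per scheduled event", {
  dmd <- c(12, 12)
  for (rep in c(1, 3)) {
    p <- build_autostim(c("a", "b", "c"), 0.02, 0.1, repeats = rep,
                        randomize = TRUE, seed = rep)
    masks <- lapply(c(a = "a", b = "b", c = "c"), full_mask, dmd_shape = dmd)
    cm <- cell_model(sensitivity = uniform_sens(dmd))
    rec <- simulate_recording(p, masks, cm, sample_rate = 2000)
    trig <- detect_triggers(rec$channels$trigger, 2000, threshold = 2.5)
    expect_length(trig, nrow(p$events))
  }
})

test_that("simulation contract errors fire", {
  dmd <- c(8, 8)
  p <- build_autostim("missing", 0.02, 0.1)
  cm <- cell_model(sensitivity = uniform_sens(dmd))
  expect_error(simulate_recording(p, list(x = full_mask("x", dmd)), cm),
               "no mask for pattern")
  p2 <- build_autostim("x", 0.02, 0.1, start = 0.1)
  expect_error(simulate_recording(p2, list(x = full_mask("x", dmd)), cm,
                                  duration = 0.05), "past the recording")
  expect_error(simulate_recording(p2, list(x = full_mask("x", dmd)), cm,
                                  sample_rate = 500), "1 kHz")
  expect_error(cell_model(sensitivity = matrix(0, 4, 4)), "zero everywhere")
})

test_that("spiking inserts a stereotyped spike and refractory clamp", {
  dmd <- c(10, 10)
  p <- build_autostim("m", exposure = 0.05, isi = 0.3, start = 0.1)
  masks <- list(m = full_mask("m", dmd))
  cm <- cell_model(sensitivity = uniform_sens(dmd), gain = 3, tau_m = 20,
                   spike_threshold = -50, spike_amp = 100)
  rec <- simulate_recording(p, masks, cm, sample_rate = 10000)
  v <- rec$channels$voltage
  expect_gt(max(v), 40)                      # spike dwarfs subthreshold drive
  # sustained suprathreshold drive fires tonically: every excursion above
  # 0 mV is one inserted spike, and the detector finds each of them
  n_spikes <- sum(v[-1] >= 0 & v[-length(v)] < 0)
  expect_gte(n_spikes, 1)
  sp <- detect_spikes(v, 10000, amp_threshold = -20, slope_threshold = 20)
  expect_equal(nrow(sp), n_spikes)
  # refractory clamp: rest-potential samples right after each spike waveform
  half_n <- round(cm$spike_dur / 2 / 1000 * 10000)
  expect_true(all(v[sp$end + half_n + 2L] == -65))
})

test_that("gaussian and dendrite sensitivity maps have the stated geometry", {
  s <- make_sensitivity_map("gaussian_blob",
                            list(center = c(50.5, 50.5), sigma = 5),
                            c(100, 100))
  am <- which(s == max(s), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(51, 51))   # pixel center (50.5, 50.5)
  # degenerate sigma -> single nonzero pixel
  s0 <- make_sensitivity_map("gaussian_blob", list(center = c(10, 10), sigma = 0),
                             c(20, 20))
  expect_equal(sum(s0 > 0), 1)
  # total mass equals the direct summation oracle
  expect_equal(sum(s), sum(vapply(seq_len(100), function(r)
    sum(exp(-((seq_len(100) - 0.5 - 50.5)^2 + (r - 0.5 - 50.5)^2) / 50)), 0)),
    tolerance = 1e-9)
  d <- make_sensitivity_map("dendrite_path",
                            list(vertices = rbind(c(5, 5), c(25, 25)), width = 2),
                            c(30, 30))
  expect_equal(max(d), 1)
  expect_gt(d[15, 15], d[5, 25])  # ridge along the path beats off-path
  expect_error(make_sensitivity_map("dendrite_path",
                                    list(vertices = rbind(c(5, 5), c(25, 25)),
                                         width = 0), c(30, 30)), "width")
})

test_that("recordings round-trip through the CSV + JSON archive", {
  dir <- withr::local_tempdir()
  dmd <- c(8, 8)
  p <- build_autostim(c("a", "b"), 0.02, 0.1, randomize = TRUE, seed = 2)
  masks <- list(a = full_mask("a", dmd), b = index_mask("b", dmd, 1:10))
  cm <- cell_model(sensitivity = uniform_sens(dmd), noise_sd = 0.5)
  rec <- simulate_recording(p, masks, cm, sample_rate = 1000, seed = 8)
  base <- file.path(dir, "rec")
  write_recording(rec, base)
  back <- read_recording(base)
  expect_equal(back$channels$voltage, rec$channels$voltage)
  expect_equal(back$channels$trigger, rec$channels$trigger)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_equal(back$meta$protocol$events, rec$meta$protocol$events)
})
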
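test_that("baseline is the mean of the pre-onset window", {
  e <- make_epoch(rep(-65, 200), onset_index = 100, sample_rate = 1000)
  expect_equal(epoch_baseline(e, 0.05), -65)
  # linear ramp -70 -> -60 over the pre window averages to -65
  ramp <- seq(-70, -60, length.out = 100)
  e2 <- make_epoch(c(ramp, rep(-60, 100)), 100, 1000)
  expect_equal(epoch_baseline(e2, 0.1), -65)
  expect_error(epoch_baseline(e, 0.2), "exceeds")
  expect_error(epoch_baseline(e, 0.0001), "no samples")
})

test_that("max-depolarization heat is peak minus baseline, with clipping", {
  e <- make_epoch(rep(-65, 300), 100, 1000)
  expect_equal(heat_max_depolarization(e, 0.1, 0.05), 0)
  # baseline -65, response peak -35 -> 30 mV
  s <- rep(-65, 300); s[150] <- -35
  e2 <- make_epoch(s, 100, 1000)
  expect_equal(heat_max_depolarization(e2, 0.1, 0.05), 30)
  # 45 mV depolarization clipped at 30
  s[150] <- -20
  e3 <- make_epoch(s, 100, 1000)
  expect_equal(heat_max_depolarization(e3, 0.1, 0.05), 45)
  expect_equal(heat_max_depolarization(e3, 0.1, 0.05, clip = 30), 30)
  # clipping is monotone and inactive below the clip
  expect_equal(heat_max_depolarization(e2, 0.1, 0.05, clip = 30), 30)
  expect_equal(heat_max_depolarization(e2, 0.1, 0.05, clip = 50), 30)
})

test_that("latency and rise time match the saturating-exponential closed form", {
  tau <- 20
  e <- make_exp_epoch(base = -65, amp = 30, tau_ms = tau, sample_rate = 10000)
  # latency(0.5) = tau * ln 2 for a saturating exponential, within one sample
  lat <- latency_evaluator(e, response_window = 0.5, fraction = 0.5)
  expect_lt(abs(lat - tau * log(2)), 1000 / 10000)
  # rise time 10->90% = tau * (ln(1/0.1) - ln(1/0.9))
  rt <- rise_time_evaluator(e, response_window = 0.5)
  expect_lt(abs(rt - tau * log(9)), 2 * 1000 / 10000)
  # ideal step at onset: latency 0, rise time 0
  st <- make_epoch(c(rep(-65, 50), rep(-35, 100)), 50, 1000)
  expect_equal(latency_evaluator(st, 0.05), 0)
  expect_equal(rise_time_evaluator(st, 0.05), 0)
  # flat trace -> undefined flag, not an error
  fl <- make_epoch(rep(-65, 150), 50, 1000)
  expect_true(is.na(latency_evaluator(fl, 0.05)))
  expect_true(is.na(rise_time_evaluator(fl, 0.05)))
})

test_that("evaluators are invariant to a constant voltage offset", {
  set.seed(30)
  e <- make_exp_epoch(base = -70, amp = 18, tau_ms = 12, sample_rate = 2000)
  e$samples <- e$samples + rnorm(length(e$samples), 0, 0.2)
  for (shift in c(-13.5, 0, 22)) {
    es <- e; es$samples <- e$samples + shift
    expect_equal(heat_max_depolarization(es, 0.1, 0.05),
                 heat_max_depolarization(e, 0.1, 0.05))
    expect_equal(latency_evaluator(es, 0.1), latency_evaluator(e, 0.1))
    expect_equal(rise_time_evaluator(es, 0.1), rise_time_evaluator(e, 0.1))
  }
})

test_that("spike detection finds threshold crossings with sufficient slope", {
  fs <- 10000
  expect_equal(nrow(detect_spikes(rep(-65, 100), fs)), 0)
  # inserted triangular spike of +100 mV
  tri <- c(seq(-65, 35, length.out = 11), seq(35, -65, length.out = 11))
  x <- c(rep(-65, 50), tri, rep(-65, 50))
  sp <- detect_spikes(x, fs, amp_threshold = -20, slope_threshold = 20)
  expect_equal(nrow(sp), 1)
  expect_true(sp$onset >= 50 && sp$end <= 80)
  expect_true(all(x[sp$onset:sp$end] >= -20))
  # slow depolarization of the same amplitude is not a spike
  slow <- c(rep(-65, 50), seq(-65, 35, length.out = 5000))
  expect_equal(nrow(detect_spikes(slow, fs, -20, 20)), 0)
  # simulator ground truth: spiking cell produces as many detections as crossings
  dmd <- c(10, 10)
  p <- build_autostim(c("m", "m2"), 0.05, 0.4, start = 0.1)
  masks <- list(m = full_mask("m", dmd), m2 = full_mask("m2", dmd))
  cm <- cell_model(sensitivity = uniform_sens(dmd), gain = 3,
                   spike_threshold = -50)
  rec <- simulate_recording(p, masks, cm, sample_rate = 10000)
  v <- rec$channels$voltage
  n_spikes <- sum(v[-1] >= 0 & v[-length(v)] < 0)  # one excursion per spike
  expect_gte(n_spikes, 2)
  expect_equal(nrow(detect_spikes(v, 10000)), n_spikes)
})

test_that("spontaneous spikes overlapping stimulation reject the epoch; evoked do not", {
  fs <- 1000
  clean <- make_epoch(rep(-65, 300), 100, fs)
  expect_true(reject_epoch(clean)$keep)
  spike_at <- function(k) {
    s <- rep(-65, 300)
    s[k:(k + 9)] <- c(seq(-65, 40, length.out = 5),
                      seq(40, -65, length.out = 5))
    make_epoch(s, 100, fs)
  }
  # spike starting 5 ms before onset, ending after onset -> spontaneous overlap
  r <- reject_epoch(spike_at(96), response_window = 0.1)
  expect_false(r$keep)
  expect_match(r$reason, "spontaneous spike overlaps stimulation")
  # evoked spike starting after onset -> kept
  expect_true(reject_epoch(spike_at(120), response_window = 0.1)$keep)
  # spike inside the baseline window -> rejected by the baseline sub-rule
  rb <- reject_epoch(spike_at(60), response_window = 0.1, baseline_window = 0.05)
  expect_false(rb$keep)
  expect_match(rb$reason, "baseline")
  # sub-rules are individually toggleable
  expect_true(reject_epoch(spike_at(60), check_baseline = FALSE)$keep)
  expect_true(reject_epoch(spike_at(96), check_overlap = FALSE,
                           check_baseline = FALSE)$keep)
})

test_that("aggregation groups by pattern, applies rejection and conserves trials", {
  fs <- 1000
  mk <- function(pid, trial, peak) {
    s <- rep(-65, 300); s[150] <- peak
    make_epoch(s, 100, fs, pattern_id = pid, trial = trial)
  }
  # 3 identical trials -> heat equals the single-trial value
  ep <- structure(list(mk("a", 1, -35), mk("a", 2, -35), mk("a", 3, -35)),
                  class = "epoch_list")
  h <- aggregate_heat(ep, params = list(response_window = 0.1))
  expect_equal(h$heat, 30)
  expect_equal(h$n_trials, 3)
  # one contaminated trial is rejected and bookkept
  bad <- mk("a", 3, -35)
  bad$samples[96:104] <- c(seq(-65, 40, length.out = 5),
                           seq(40, -65, length.out = 4))
  ep2 <- structure(list(mk("a", 1, -35), mk("a", 2, -29), bad),
                   class = "epoch_list")
  h2 <- aggregate_heat(ep2, params = list(response_window = 0.1))
  expect_equal(h2$n_trials, 2)
  expect_equal(h2$n_rejected, 1)
  expect_equal(h2$heat, mean(c(30, 36)))
  expect_match(attr(h2, "trials")$a$reason[3], "spontaneous")
  # interleaved patterns group correctly; trials conserved
  ep3 <- structure(list(mk("x", 1, -40), mk("y", 1, -30), mk("x", 2, -40),
                        mk("y", 2, -30)), class = "epoch_list")
  h3 <- aggregate_heat(ep3, params = list(response_window = 0.1))
  expect_setequal(h3$pattern_id, c("x", "y"))
  expect_equal(sum(h3$n_trials + h3$n_rejected), length(ep3))
  expect_equal(h3$heat[h3$pattern_id == "x"], 25)
  expect_error(aggregate_heat(ep3, evaluator = "nope"), "max_depolarization")
})

test_that("evaluator registry is queryable before invocation", {
  expect_true(all(c("max_depolarization", "latency", "rise_time") %in%
                    list_evaluators()))
  pd <- evaluator_params("max_depolarization")
  expect_equal(pd$name, c("response_window", "baseline_window", "clip"))
  expect_false(any(pd$required))
  # a custom evaluator registers through the same contract
  register_evaluator(evaluator_spec(
    "area_under_curve",
    function(epoch, params) {
      b <- epoch_baseline(epoch, params$baseline_window)
      idx <- (epoch$onset_index + 1):length(epoch$samples)
      sum(epoch$samples[idx] - b) / epoch$sample_rate
    },
    params = list(evaluator_param("baseline_window", default = 0.05, units = "s")),
    units = "mV*s"))
  expect_true("area_under_curve" %in% list_evaluators())
  e <- make_epoch(c(rep(-65, 50), rep(-55, 50)), 50, 1000)
  h <- aggregate_heat(structure(list(e), class = "epoch_list"),
                      evaluator = "area_under_curve", reject = FALSE)
  expect_equal(h$heat, 10 * 50 / 1000)
})

test_that("integration index is zero for a linear cell and positive across a spike threshold", {
  dmd <- c(16, 16)
  masks <- list(A = index_mask("A", dmd, 1:60), B = index_mask("B", dmd, 100:160),
                `A+B` = index_mask("A+B", dmd, c(1:60, 100:160)))
  run_battery <- function(cm) {
    p <- build_integration_battery("A", "B", exposure = 0.02, isi = 0.4,
                                   repeats = 3, seed = 17)
    rec <- simulate_recording(p, masks, cm, sample_rate = 10000)
    ep <- segment_epochs(rec, p, pre = 0.05, post = 0.1)
    h <- aggregate_heat(ep, params = list(response_window = 0.05))
    idx <- function(pid) h$heat[h$pattern_id == pid]
    integration_index(idx("A"), idx("B"), idx("A+B"))
  }
  lin <- cell_model(sensitivity = uniform_sens(dmd), gain = 4, tau_m = 15)
  expect_lt(abs(run_battery(lin)), 0.1)
  # spike threshold between the single and combined drives -> supralinear
  spk <- cell_model(sensitivity = uniform_sens(dmd), gain = 4, tau_m = 15,
                    spike_threshold = -52)
  expect_gt(run_battery(spk), 0)
  # exact arithmetic and undefined propagation
  expect_equal(integration_index(3, 4, 7), 0)
  expect_true(is.na(integration_index(3, NA, 7)))
})
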
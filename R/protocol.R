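#' Stimulation protocols
#'
#' A protocol is an explicit timeline of pattern exposures. Each event has a
#' TTL trigger time and a stimulus onset time (`onset = trigger +
#' trig_delay`, emulating the DMD's trigger-delay property); the
#' inter-stimulus interval (ISI) is defined onset-to-onset. Builders:
#'
#' * [build_autostim()] — one pattern per event, optionally shuffled
#'   independently per repeat (seeded Fisher-Yates);
#' * [build_pairedstim()] — two patterns per trial, the second delayed by a
#'   fixed latency;
#' * [build_integration_battery()] — each repeat stimulates pattern A alone,
#'   B alone, and A and B together (grouped mask), in randomized order.
#'
#' @name stim_protocol
NULL

new_protocol <- function(mode, events, isi, trig_delay, repeats, randomize,
                         seed, exposure, paired_latency = NULL,
                         metadata = list()) {
  events$index <- seq_len(nrow(events))
  p <- structure(list(mode = mode, events = events,
                      inter_stimulus_interval = isi, trig_delay = trig_delay,
                      repeats = repeats, randomize = randomize, seed = seed,
                      exposure = exposure, paired_latency = paired_latency,
                      metadata = metadata),
                 class = "stim_protocol")
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  ev <- p$events
  if (nrow(ev) == 0L) stopf("protocol has no events")
  if (p$mode == "pairedstim") {
    # a zero-latency pair degenerates to simultaneous A/B onsets: allow ties
    if (any(diff(ev$trigger_time) < 0)) stopf("event trigger times must be non-decreasing")
  } else if (any(diff(ev$trigger_time) <= 0)) {
    stopf("event trigger times must be strictly increasing")
  }
  if (any(ev$onset_time < ev$trigger_time)) stopf("onset before trigger")
  if (any(ev$exposure <= 0)) stopf("exposure must be > 0")
  # single-DMD constraint: exposures must not overlap, except the deliberate
  # A/B overlap inside a paired trial when paired_latency < exposure
  if (p$mode != "pairedstim") {
    ends <- ev$onset_time + ev$exposure
    if (any(ev$onset_time[-1] < ends[-nrow(ev)] - 1e-12))
      stopf("overlapping exposures in protocol")
  }
  invisible(p)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol %s> %d events, %d patterns, isi %g s, exposure %g s%s\n",
              x$mode, nrow(x$events), length(unique(x$events$pattern_id)),
              x$inter_stimulus_interval, x$exposure,
              if (isTRUE(x$randomize)) sprintf(", randomized (seed %s)", x$seed) else ""))
  invisible(x)
}

#' Build an automated stimulation sequence
#'
#' Generates `repeats x length(pattern_ids)` events. With `randomize =
#' TRUE`, each repeat's pattern order is an independent permutation drawn by
#' a seeded Fisher-Yates shuffle; the realized order is stored in
#' `metadata$order` so any downstream analysis can invert it.
#'
#' @param pattern_ids character vector of pattern (mask) ids, length >= 1.
#' @param exposure exposure duration per pattern, seconds (> 0).
#' @param isi onset-to-onset inter-stimulus interval, seconds (>= exposure).
#' @param repeats number of repeats of the full pattern list.
#' @param randomize shuffle pattern order independently per repeat.
#' @param seed integer RNG seed for the shuffle (recorded in the protocol).
#' @param trig_delay delay between the TTL trigger and stimulus onset,
#'   seconds.
#' @param start onset time of the first stimulus, seconds; leaves room for
#'   a pre-stimulus baseline window in the recording.
#' @return a `stim_protocol`.
#' @export
#' @examples
#' p <- build_autostim(c("a", "b", "c"), exposure = 0.02, isi = 0.2,
#'                     repeats = 2, randomize = TRUE, seed = 7)
#' p$events$pattern_id
build_autostim <- function(pattern_ids, exposure, isi, repeats = 1L,
                           randomize = FALSE, seed = NULL, trig_delay = 0,
                           start = 0.2) {
  if (length(pattern_ids) < 1L) stopf("need at least one pattern")
  if (exposure <= 0) stopf("exposure must be > 0")
  if (isi < exposure) stopf("isi (%g s) must be >= exposure (%g s)", isi, exposure)
  if (repeats < 1L) stopf("repeats must be >= 1")
  order <- with_seed(seed, {
    unlist(lapply(seq_len(repeats), function(r)
      if (randomize) fisher_yates(pattern_ids) else pattern_ids))
  })
  n <- length(order)
  onsets <- start + trig_delay + (seq_len(n) - 1L) * isi
  ev <- data.frame(pattern_id = order, condition = order,
                   trigger_time = onsets - trig_delay, onset_time = onsets,
                   exposure = exposure,
                   rep = rep(seq_len(repeats), each = length(pattern_ids)),
                   stringsAsFactors = FALSE)
  autolog("build_autostim: %d patterns x %d repeats, randomize=%s, seed=%s",
          length(pattern_ids), repeats, randomize, seed %||% "NULL")
  new_protocol("autostim", ev, isi, trig_delay, repeats, randomize, seed,
               exposure, metadata = list(order = order))
}

#' Build a paired (delayed two-pattern) stimulation protocol
#'
#' Each trial exposes pattern A at the trial start and pattern B
#' `paired_latency` seconds later; trials are separated by `isi`
#' (A-onset-to-A-onset). The two patterns may be identical, independent, or
#' partially overlapping; a latency shorter than the exposure deliberately
#' overlaps the two exposures.
#'
#' @param pattern_a,pattern_b pattern ids.
#' @param paired_latency delay of B after A within a trial, seconds (>= 0).
#' @inheritParams build_autostim
#' @return a `stim_protocol` with condition labels `"A"`/`"B"`.
#' @export
build_pairedstim <- function(pattern_a, pattern_b, paired_latency, exposure,
                             isi, repeats = 1L, seed = NULL, trig_delay = 0,
                             start = 0.2) {
  if (paired_latency < 0) stopf("paired_latency must be >= 0")
  if (exposure <= 0) stopf("exposure must be > 0")
  if (isi < exposure + paired_latency)
    stopf("isi must cover one full paired trial (exposure + latency)")
  if (repeats < 1L) stopf("repeats must be >= 1")
  a_on <- start + trig_delay + (seq_len(repeats) - 1L) * isi
  ev <- data.frame(
    pattern_id = rep(c(pattern_a, pattern_b), times = repeats),
    condition = rep(c("A", "B"), times = repeats),
    onset_time = as.vector(rbind(a_on, a_on + paired_latency)),
    exposure = exposure,
    rep = rep(seq_len(repeats), each = 2L),
    stringsAsFactors = FALSE)
  ev$trigger_time <- ev$onset_time - trig_delay
  autolog("build_pairedstim: %s + %s, latency %g s, %d repeats",
          pattern_a, pattern_b, paired_latency, repeats)
  new_protocol("pairedstim", ev, isi, trig_delay, repeats, FALSE, seed,
               exposure, paired_latency = paired_latency)
}

#' Build a dendritic-integration battery
#'
#' Per repeat, three conditions are scheduled in (optionally) randomized
#' order: pattern A alone, pattern B alone, and A and B simultaneously (the
#' grouped mask, id `"A+B"`). Comparing the combined response with the sum
#' of the individual responses via [integration_index()] quantifies
#' supralinear summation.
#'
#' @inheritParams build_pairedstim
#' @param randomize shuffle condition order independently per repeat.
#' @return a `stim_protocol` with condition labels `"A"`, `"B"`, `"AB"`.
#' @export
build_integration_battery <- function(pattern_a, pattern_b, exposure, isi,
                                      repeats = 1L, randomize = TRUE,
                                      seed = NULL, trig_delay = 0,
                                      start = 0.2) {
  if (identical(pattern_a, pattern_b)) stopf("pattern_a and pattern_b must differ")
  if (exposure <= 0) stopf("exposure must be > 0")
  if (isi < exposure) stopf("isi must be >= exposure")
  if (repeats < 1L) stopf("repeats must be >= 1")
  combined <- paste0(pattern_a, "+", pattern_b)
  conds <- c("A", "B", "AB")
  cond_order <- with_seed(seed, {
    unlist(lapply(seq_len(repeats), function(r)
      if (randomize) fisher_yates(conds) else conds))
  })
  pat <- c(A = pattern_a, B = pattern_b, AB = combined)[cond_order]
  n <- length(cond_order)
  onsets <- start + trig_delay + (seq_len(n) - 1L) * isi
  ev <- data.frame(pattern_id = unname(pat), condition = cond_order,
                   trigger_time = onsets - trig_delay, onset_time = onsets,
                   exposure = exposure, rep = rep(seq_len(repeats), each = 3L),
                   stringsAsFactors = FALSE)
  autolog("build_integration_battery: %s vs %s, %d repeats, seed=%s",
          pattern_a, pattern_b, repeats, seed %||% "NULL")
  new_protocol("integration", ev, isi, trig_delay, repeats, randomize, seed,
               exposure, metadata = list(order = cond_order,
                                         combined_id = combined))
}

#' Serialize a protocol to / from JSON
#'
#' Round-tripping through JSON reproduces the protocol exactly (full-
#' precision numbers).
#'
#' @param protocol a `stim_protocol`.
#' @param path file path.
#' @return `protocol_to_json` invisibly returns `path`; `protocol_from_json`
#'   the reconstructed protocol.
#' @export
protocol_to_json <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname protocol_to_json
#' @export
protocol_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(x$events, stringsAsFactors = FALSE)
  new_protocol(x$mode, ev, x$inter_stimulus_interval, x$trig_delay,
               x$repeats, isTRUE(x$randomize),
               x$seed, x$exposure,
               paired_latency = x$paired_latency,
               metadata = lapply(x$metadata, unlist))
}
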
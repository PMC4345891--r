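#' Scale a raw signal to physical units
#'
#' Linear amplifier scaling `out = raw * gain + offset`, applied manually so
#' recorded signal values match physical data values (e.g. a head-stage
#' output recorded in volts mapped back to membrane millivolts).
#'
#' @param raw numeric trace.
#' @param gain scale factor (nonzero).
#' @param offset additive offset, output units.
#' @return scaled numeric trace.
#' @export
scale_signal <- function(raw, gain, offset = 0) {
  if (gain == 0) stopf("gain must be nonzero")
  raw * gain + offset
}

#' Detect trigger pulse onsets
#'
#' Finds rising threshold crossings in the trigger channel: sample `k` with
#' `x[k-1] < threshold <= x[k]`. Crossings closer than `min_gap` to the
#' previously accepted one are discarded (debounce). With
#' `edge = "falling"` the trace is negated first.
#'
#' @param trigger_trace numeric trace (V).
#' @param sample_rate Hz.
#' @param threshold crossing threshold; default: midpoint of the trace's
#'   min and max.
#' @param min_gap minimum separation between accepted triggers, seconds.
#' @param edge `"rising"` (TTL pulses precede each exposure) or `"falling"`.
#' @return integer vector of onset sample indices (1-based).
#' @export
#' @examples
#' x <- rep(c(0, 0, 5, 5, 0), 3)
#' detect_triggers(x, 1000, min_gap = 0)
detect_triggers <- function(trigger_trace, sample_rate, threshold = NULL,
                            min_gap = 0.001, edge = c("rising", "falling")) {
  edge <- match.arg(edge)
  if (min_gap < 0) stopf("min_gap must be >= 0")
  x <- as.numeric(trigger_trace)
  if (length(x) < 2L) return(integer())
  if (edge == "falling") x <- -x
  threshold <- threshold %||% ((min(x) + max(x)) / 2)
  idx <- which(x[-1L] >= threshold & x[-length(x)] < threshold) + 1L
  if (length(idx) < 2L || min_gap == 0) return(idx)
  gap_n <- round(min_gap * sample_rate)
  keep <- idx[1]
  for (i in idx[-1]) if (i - keep[length(keep)] >= gap_n) keep <- c(keep, i)
  keep
}

#' Cut a recording into per-stimulus epochs
#'
#' Detects the DMD output-trigger pulses, matches them ordinally to the
#' protocol's events (the k-th trigger belongs to the k-th scheduled event,
#' which inverts any recorded randomization), and slices the voltage trace
#' into windows `[onset - pre, onset + post)` where
#' `onset = trigger + trig_delay`. A trigger/event count mismatch is an
#' error reporting both counts; an epoch whose window would leave the
#' recording is excluded with a warning and recorded in the
#' `"truncated"` attribute.
#'
#' @param recording a `rig_recording` (or any list with `sample_rate` and
#'   `channels$voltage` / `channels$trigger`).
#' @param protocol the `stim_protocol` that produced the recording.
#' @param pre pre-onset window, seconds.
#' @param post post-onset window, seconds.
#' @param trig_delay trigger-to-onset delay, seconds; default: the
#'   protocol's.
#' @param threshold trigger threshold override (see [detect_triggers()]).
#' @param min_gap trigger debounce, seconds; default: half the protocol's
#'   inter-stimulus interval.
#' @return list of epochs (class `"epoch_list"`); each epoch holds
#'   `pattern_id`, `condition`, `trial`, `samples` (mV), `onset_index`
#'   (number of pre-onset samples, `= round(pre * sample_rate)`), and
#'   `sample_rate`.
#' @export
segment_epochs <- function(recording, protocol, pre = 0.05, post = 0.5,
                           trig_delay = NULL, threshold = NULL,
                           min_gap = NULL) {
  fs <- recording$sample_rate
  trig_delay <- trig_delay %||% protocol$trig_delay %||% 0
  min_gap <- min_gap %||% (protocol$inter_stimulus_interval / 2)
  trig <- detect_triggers(recording$channels$trigger, fs,
                          threshold = threshold, min_gap = min_gap)
  ev <- protocol$events
  if (length(trig) != nrow(ev))
    stopf("trigger/event count mismatch: %d triggers detected, %d events scheduled",
          length(trig), nrow(ev))
  pre_n <- as.integer(round(pre * fs))
  post_n <- as.integer(round(post * fs))
  if (pre_n + post_n < 1L) stopf("empty epoch window")
  v <- recording$channels$voltage
  n <- length(v)
  trial <- stats::ave(seq_len(nrow(ev)), ev$pattern_id, FUN = seq_along)
  epochs <- list()
  truncated <- character()
  for (k in seq_len(nrow(ev))) {
    onset <- trig[k] + round(trig_delay * fs)
    lo <- onset - pre_n
    hi <- onset + post_n - 1L
    if (lo < 1L || hi > n) {
      truncated <- c(truncated, sprintf("event %d (%s)", k, ev$pattern_id[k]))
      next
    }
    epochs[[length(epochs) + 1L]] <- structure(
      list(pattern_id = ev$pattern_id[k], condition = ev$condition[k],
           trial = trial[k], samples = v[lo:hi], onset_index = pre_n,
           sample_rate = fs),
      class = "stim_epoch")
  }
  if (length(truncated))
    warnf("excluded %d truncated epoch(s): %s", length(truncated),
          paste(truncated, collapse = "; "))
  structure(epochs, class = "epoch_list", truncated = truncated)
}

#' @export
print.epoch_list <- function(x, ...) {
  pats <- vapply(x, `[[`, "", "pattern_id")
  cat(sprintf("<epoch_list> %d epochs, %d patterns\n",
              length(x), length(unique(pats))))
  invisible(x)
}

#' Write / read an epochs archive
#'
#' Stacked sample slices as CSV (one column per epoch) plus a JSON index
#' (pattern, condition, trial, onset index, sample rate).
#'
#' @param epochs an `"epoch_list"` from [segment_epochs()].
#' @param path base path (no extension).
#' @return `write_epochs` invisibly returns the paths; `read_epochs` the
#'   reconstructed epoch list.
#' @export
write_epochs <- function(epochs, path) {
  if (length(epochs) == 0L) stopf("no epochs to write")
  m <- vapply(epochs, `[[`, numeric(length(epochs[[1]]$samples)), "samples")
  colnames(m) <- sprintf("epoch_%d", seq_along(epochs))
  csv <- paste0(path, ".csv")
  utils::write.csv(m, csv, row.names = FALSE)
  idx <- list(
    pattern_id = vapply(epochs, `[[`, "", "pattern_id"),
    condition = vapply(epochs, `[[`, "", "condition"),
    trial = vapply(epochs, `[[`, 0, "trial"),
    onset_index = epochs[[1]]$onset_index,
    sample_rate = epochs[[1]]$sample_rate)
  json <- paste0(path, ".json")
  jsonlite::write_json(idx, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  m <- as.matrix(utils::read.csv(paste0(path, ".csv")))
  idx <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  epochs <- lapply(seq_len(ncol(m)), function(i) structure(
    list(pattern_id = idx$pattern_id[i], condition = idx$condition[i],
         trial = idx$trial[i], samples = unname(m[, i]),
         onset_index = idx$onset_index, sample_rate = idx$sample_rate),
    class = "stim_epoch"))
  structure(epochs, class = "epoch_list", truncated = character())
}
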
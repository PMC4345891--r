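#' Baseline membrane potential of an epoch
#'
#' Mean of the samples in the `baseline_window` seconds immediately
#' preceding stimulus onset (`[onset - baseline_window, onset)`).
#'
#' @param epoch a `"stim_epoch"` (see [segment_epochs()]).
#' @param baseline_window window length, seconds; must fit inside the
#'   epoch's pre-onset span and contain at least one sample.
#' @return baseline, mV.
#' @export
epoch_baseline <- function(epoch, baseline_window = 0.05) {
  fs <- epoch$sample_rate
  bn <- round(baseline_window * fs)
  if (bn < 1L) stopf("baseline window contains no samples")
  if (bn > epoch$onset_index)
    stopf("baseline window (%g s) exceeds the epoch's pre-onset span (%g s)",
          baseline_window, epoch$onset_index / fs)
  mean(epoch$samples[(epoch$onset_index - bn + 1L):epoch$onset_index])
}

# response-window sample indices: [onset, onset + dt)
response_indices <- function(epoch, response_window) {
  rn <- round(response_window * epoch$sample_rate)
  if (rn < 1L) stopf("response window contains no samples")
  hi <- epoch$onset_index + rn
  if (hi > length(epoch$samples))
    stopf("response window (%g s) exceeds the epoch's post-onset span", response_window)
  (epoch$onset_index + 1L):hi
}

#' Maximum-depolarization heat evaluator
#'
#' The default heat statistic: the difference between the maximum membrane
#' potential within the response window after stimulus onset and the mean
#' membrane potential in the baseline window before onset. With `clip` set,
#' any larger depolarization is reported as the clip value, so that action
#' potentials do not dwarf subthreshold responses on a heat map (the
#' conventional presentation clip is 30 mV).
#'
#' @inheritParams epoch_baseline
#' @param response_window response interval after onset, seconds.
#' @param clip ceiling on the returned heat, mV, or `NULL` for no clipping.
#' @return heat, mV (ties in the max resolve to the earliest sample).
#' @export
heat_max_depolarization <- function(epoch, response_window = 0.1,
                                    baseline_window = 0.05, clip = NULL) {
  b <- epoch_baseline(epoch, baseline_window)
  raw <- max(epoch$samples[response_indices(epoch, response_window)]) - b
  if (!is.null(clip)) min(raw, clip) else raw
}

#' Latency and rise-time evaluators
#'
#' `latency_evaluator`: first time after onset at which the
#' baseline-subtracted voltage reaches `fraction` of its peak (default: the
#' half-maximum), in ms. `rise_time_evaluator`: time from 10% to 90% of the
#' peak-above-baseline, linearly interpolated between samples, in ms. Both
#' return `NA` (undefined, not an error) when the peak does not exceed the
#' baseline.
#'
#' @inheritParams heat_max_depolarization
#' @param fraction peak fraction for the latency, in (0, 1).
#' @return milliseconds, or `NA` if undefined.
#' @export
latency_evaluator <- function(epoch, response_window = 0.1, fraction = 0.5,
                              baseline_window = 0.05) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  b <- epoch_baseline(epoch, baseline_window)
  idx <- response_indices(epoch, response_window)
  v <- epoch$samples[idx] - b
  peak <- max(v)
  if (peak <= 0) return(NA_real_)
  k <- which(v >= fraction * peak)[1]
  (k - 1L) / epoch$sample_rate * 1000
}

#' @rdname latency_evaluator
#' @export
rise_time_evaluator <- function(epoch, response_window = 0.1,
                                baseline_window = 0.05) {
  b <- epoch_baseline(epoch, baseline_window)
  idx <- response_indices(epoch, response_window)
  v <- epoch$samples[idx] - b
  kp <- which.max(v)
  peak <- v[kp]
  if (peak <= 0) return(NA_real_)
  t_cross <- function(level) {
    k <- which(v[seq_len(kp)] >= level)[1]
    if (is.na(k)) return(NA_real_)
    if (k == 1L) return(0)
    # linear interpolation between samples k-1 and k
    (k - 2L + (level - v[k - 1L]) / (v[k] - v[k - 1L])) / epoch$sample_rate * 1000
  }
  t90 <- t_cross(0.9 * peak)
  t10 <- t_cross(0.1 * peak)
  t90 - t10
}

#' Detect action potentials in a trace
#'
#' A spike starts at an upward crossing of `amp_threshold` whose
#' instantaneous slope is at least `slope_threshold`, and spans until the
#' voltage falls back below `amp_threshold`.
#'
#' @param trace numeric voltage trace, mV.
#' @param sample_rate Hz.
#' @param amp_threshold amplitude threshold, mV.
#' @param slope_threshold minimum slope at the crossing, mV/ms.
#' @return data frame with columns `onset` and `end` (sample indices,
#'   inclusive span of the above-threshold samples); zero rows when no
#'   spike is found.
#' @export
detect_spikes <- function(trace, sample_rate, amp_threshold = -20,
                          slope_threshold = 20) {
  x <- as.numeric(trace)
  n <- length(x)
  if (n < 2L) return(data.frame(onset = integer(), end = integer()))
  slope <- c(0, diff(x)) * sample_rate / 1000   # mV/ms
  up <- which(x[-1L] >= amp_threshold & x[-n] < amp_threshold) + 1L
  up <- up[slope[up] >= slope_threshold]
  onsets <- integer(); ends <- integer()
  last_end <- 0L
  for (k in up) {
    if (k <= last_end) next
    below <- which(x[k:n] < amp_threshold)[1]
    e <- if (is.na(below)) n else k + below - 2L
    onsets <- c(onsets, k); ends <- c(ends, e)
    last_end <- e
  }
  data.frame(onset = onsets, end = ends)
}

#' Artifact rejection for one epoch
#'
#' Implements the spontaneous-activity scan: an epoch is discarded when a
#' spike that began *before* stimulus onset overlaps the stimulation
#' response window (a spontaneous action potential contaminating the
#' measurement), or when any spike falls inside the baseline window. Spikes
#' that start after onset are treated as evoked and kept. The two sub-rules
#' can be toggled independently.
#'
#' @inheritParams heat_max_depolarization
#' @param amp_threshold,slope_threshold spike detector settings
#'   (see [detect_spikes()]).
#' @param check_overlap reject on spontaneous spikes overlapping the
#'   response window.
#' @param check_baseline reject on spikes inside the baseline window.
#' @return `list(keep = logical, reason = character)`; `reason` is `""`
#'   when kept.
#' @export
reject_epoch <- function(epoch, response_window = 0.1,
                         baseline_window = 0.05, amp_threshold = -20,
                         slope_threshold = 20, check_overlap = TRUE,
                         check_baseline = TRUE) {
  fs <- epoch$sample_rate
  sp <- detect_spikes(epoch$samples, fs, amp_threshold, slope_threshold)
  onset <- epoch$onset_index + 1L
  if (nrow(sp)) {
    resp_end <- epoch$onset_index + round(response_window * fs)
    bn <- round(baseline_window * fs)
    base_lo <- epoch$onset_index - bn + 1L
    for (i in seq_len(nrow(sp))) {
      spontaneous <- sp$onset[i] < onset
      if (check_overlap && spontaneous && sp$end[i] >= onset &&
          sp$onset[i] <= resp_end)
        return(list(keep = FALSE,
                    reason = "spontaneous spike overlaps stimulation"))
      if (check_baseline && sp$onset[i] <= epoch$onset_index &&
          sp$end[i] >= base_lo && spontaneous)
        return(list(keep = FALSE, reason = "spike in baseline window"))
    }
  }
  list(keep = TRUE, reason = "")
}

# --- evaluator registry -------------------------------------------------

#' Evaluator registry
#'
#' Heat-map evaluation functions are pluggable. An evaluator spec names the
#' function and declares its ordered parameter descriptors (name, type,
#' default, units), which callers — including the CLI — can query *before*
#' invoking the evaluator to learn what parameters must be passed. Built-in
#' evaluators: `max_depolarization` (the default heat statistic),
#' `latency`, `rise_time`.
#'
#' @param name unique evaluator name.
#' @param fn function `(epoch, params)` returning a scalar (or `NA` for an
#'   undefined result).
#' @param params list of descriptors from [evaluator_param()].
#' @param units units of the returned scalar.
#' @return `evaluator_spec` returns the spec; `register_evaluator`
#'   registers it (invisibly); `evaluator_params` returns the parameter
#'   descriptor table for a registered name; `list_evaluators` the
#'   registered names.
#' @export
evaluator_spec <- function(name, fn, params = list(), units = "mV") {
  stopifnot(is.character(name), is.function(fn))
  pn <- vapply(params, `[[`, "", "name")
  if (anyDuplicated(pn)) stopf("duplicate parameter names in evaluator '%s'", name)
  structure(list(name = name, fn = fn, params = params, units = units),
            class = "evaluator_spec")
}

#' @rdname evaluator_spec
#' @param type parameter type (`"numeric"`, `"logical"`, ...).
#' @param default default value; `NULL` with `required = TRUE` marks a
#'   mandatory parameter.
#' @param required must the caller supply a value?
#' @export
evaluator_param <- function(name, type = "numeric", default = NULL,
                            units = "", required = is.null(default)) {
  list(name = name, type = type, default = default, units = units,
       required = required)
}

#' @rdname evaluator_spec
#' @param spec an `evaluator_spec`.
#' @export
register_evaluator <- function(spec) {
  stopifnot(inherits(spec, "evaluator_spec"))
  .optomap$evaluators[[spec$name]] <- spec
  invisible(spec)
}

#' @rdname evaluator_spec
#' @export
list_evaluators <- function() names(.optomap$evaluators)

#' @rdname evaluator_spec
#' @export
evaluator_params <- function(name) {
  spec <- get_evaluator(name)
  do.call(rbind, lapply(spec$params, function(p)
    data.frame(name = p$name, type = p$type,
               default = if (is.null(p$default)) NA else p$default,
               units = p$units, required = p$required,
               stringsAsFactors = FALSE)))
}

get_evaluator <- function(name) {
  spec <- .optomap$evaluators[[name]]
  if (is.null(spec))
    stopf("unknown evaluator '%s'; registered: %s", name,
          paste(list_evaluators(), collapse = ", "))
  spec
}

resolve_params <- function(spec, params) {
  out <- list()
  for (p in spec$params) {
    v <- params[[p$name]] %||% p$default
    if (is.null(v) && p$required)
      stopf("evaluator '%s' requires parameter '%s'", spec$name, p$name)
    out[[p$name]] <- v
  }
  out
}

register_builtin_evaluators <- function() {
  register_evaluator(evaluator_spec(
    "max_depolarization",
    function(epoch, params) heat_max_depolarization(
      epoch, params$response_window, params$baseline_window, params$clip),
    params = list(
      evaluator_param("response_window", default = 0.1, units = "s"),
      evaluator_param("baseline_window", default = 0.05, units = "s"),
      evaluator_param("clip", default = NULL, units = "mV", required = FALSE)),
    units = "mV"))
  register_evaluator(evaluator_spec(
    "latency",
    function(epoch, params) latency_evaluator(
      epoch, params$response_window, params$fraction, params$baseline_window),
    params = list(
      evaluator_param("response_window", default = 0.1, units = "s"),
      evaluator_param("fraction", default = 0.5, units = ""),
      evaluator_param("baseline_window", default = 0.05, units = "s")),
    units = "ms"))
  register_evaluator(evaluator_spec(
    "rise_time",
    function(epoch, params) rise_time_evaluator(
      epoch, params$response_window, params$baseline_window),
    params = list(
      evaluator_param("response_window", default = 0.1, units = "s"),
      evaluator_param("baseline_window", default = 0.05, units = "s")),
    units = "ms"))
}

# --- aggregation --------------------------------------------------------

#' Aggregate epochs into per-pattern heat results
#'
#' Groups epochs by pattern, applies artifact rejection, evaluates each
#' surviving trial with the named evaluator, and reports the per-pattern
#' mean ("heat"). Per-trial values, rejection reasons and the mean waveform
#' of the surviving trials are kept so either the per-trial or the
#' averaged-waveform view can be reproduced.
#'
#' @param epochs an `"epoch_list"`.
#' @param evaluator registered evaluator name (see [evaluator_spec()]).
#' @param params named list of evaluator parameter overrides.
#' @param reject apply [reject_epoch()] before evaluating.
#' @param reject_params named list of arguments passed to [reject_epoch()].
#' @return data frame of class `"heat_result"`: `pattern_id`, `heat`
#'   (`NA` when every trial was rejected), `n_trials` (used), `n_rejected`;
#'   attributes `trials` (per-pattern values/keep flags/reasons),
#'   `waveforms` (per-pattern mean trace of kept trials), `evaluator`,
#'   `params`, `units`.
#' @export
aggregate_heat <- function(epochs, evaluator = "max_depolarization",
                           params = list(), reject = TRUE,
                           reject_params = list()) {
  if (length(epochs) == 0L) stopf("no epochs to aggregate")
  fs <- unique(vapply(epochs, `[[`, 0, "sample_rate"))
  if (length(fs) != 1L) stopf("epochs have mixed sample rates")
  spec <- get_evaluator(evaluator)
  pars <- resolve_params(spec, params)
  pats <- vapply(epochs, `[[`, "", "pattern_id")
  upat <- unique(pats)
  rows <- vector("list", length(upat))
  trials <- list()
  waveforms <- list()
  for (i in seq_along(upat)) {
    pid <- upat[i]
    es <- epochs[pats == pid]
    keep <- logical(length(es)); reasons <- character(length(es))
    vals <- rep(NA_real_, length(es))
    for (j in seq_along(es)) {
      dec <- if (reject) do.call(reject_epoch, c(list(es[[j]]), reject_params))
             else list(keep = TRUE, reason = "")
      keep[j] <- dec$keep; reasons[j] <- dec$reason
      if (dec$keep) vals[j] <- spec$fn(es[[j]], pars)
    }
    kept_vals <- vals[keep & !is.na(vals)]
    rows[[i]] <- data.frame(
      pattern_id = pid,
      heat = if (length(kept_vals)) mean(kept_vals) else NA_real_,
      n_trials = sum(keep), n_rejected = sum(!keep),
      stringsAsFactors = FALSE)
    trials[[pid]] <- data.frame(trial = vapply(es, `[[`, 0, "trial"),
                                value = vals, kept = keep, reason = reasons,
                                stringsAsFactors = FALSE)
    if (any(keep)) {
      waveforms[[pid]] <- rowMeans(
        vapply(es[keep], `[[`, numeric(length(es[[1]]$samples)), "samples"))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("heat_result", "data.frame")
  attr(out, "trials") <- trials
  attr(out, "waveforms") <- waveforms
  attr(out, "evaluator") <- evaluator
  attr(out, "params") <- pars
  attr(out, "units") <- spec$units
  autolog("aggregate_heat: evaluator=%s, %d patterns, %d epochs",
          evaluator, length(upat), length(epochs))
  out
}

#' Integration index of paired stimulation
#'
#' `heat_AB - (heat_A + heat_B)`: the excess depolarization of simultaneous
#' stimulation over the sum of the individual responses. Zero for a linear
#' cell; a positive index indicates supralinear (e.g. dendritic) summation.
#'
#' @param heat_a,heat_b,heat_ab per-condition heat values, mV.
#' @return index, mV; `NA` if any input is undefined.
#' @export
integration_index <- function(heat_a, heat_b, heat_ab) {
  if (any(is.na(c(heat_a, heat_b, heat_ab)))) return(NA_real_)
  heat_ab - (heat_a + heat_b)
}

#' Heat results as plain tables
#'
#' @param heat a `"heat_result"`.
#' @param path base path; writes `<path>.json` (full records incl. trial
#'   values) and `<path>.csv` (pattern_id, heat, n_trials, n_rejected).
#' @return invisibly, the two paths.
#' @export
write_heat_results <- function(heat, path) {
  csv <- paste0(path, ".csv")
  utils::write.csv(as.data.frame(heat), csv, row.names = FALSE)
  json <- paste0(path, ".json")
  jsonlite::write_json(list(results = as.data.frame(heat),
                            trials = attr(heat, "trials"),
                            evaluator = attr(heat, "evaluator"),
                            params = attr(heat, "params"),
                            units = attr(heat, "units")),
                       json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(c(csv = csv, json = json))
}
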
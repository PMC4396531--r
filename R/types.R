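#' Construct a spike-train set
#'
#' Container for one multi-electrode recording session: electrode-resolved
#' action-potential timestamps, globally sorted in time. Times are seconds from
#' recording start; rates elsewhere in the package are network-summed spikes/ms.
#'
#' @param electrode_id integer vector of electrode indices (0-based).
#' @param time_s numeric vector of spike times in seconds, same length.
#' @param duration recording duration in seconds; defaults to `max(time_s)`.
#' @param n_electrodes number of electrodes; defaults to `max(electrode_id) + 1`.
#' @return An object of class `spike_train_set`: a list with elements
#'   `spikes` (data.frame with columns `electrode_id`, `time_s`, sorted by
#'   time), `duration` and `n_electrodes`.
#' @export
spike_train_set <- function(electrode_id, time_s, duration = NULL,
                            n_electrodes = NULL) {
  if (length(electrode_id) != length(time_s))
    stop("electrode_id and time_s must have the same length")
  if (length(time_s) == 0L) stop("no spikes")
  if (any(!is.finite(time_s)) || any(time_s < 0))
    stop("spike times must be finite and >= 0")
  id <- as.integer(electrode_id)
  if (any(is.na(id)) || any(id < 0L))
    stop("electrode ids must be non-negative integers")
  if (is.null(duration)) duration <- max(time_s)
  if (is.null(n_electrodes)) n_electrodes <- max(id) + 1L
  if (any(time_s > duration + 1e-9))
    stop("spike times exceed the stated duration")
  if (any(id >= n_electrodes))
    stop("electrode id >= n_electrodes")
  ord <- order(time_s, id)
  structure(
    list(spikes = data.frame(electrode_id = id[ord], time_s = time_s[ord]),
         duration = as.numeric(duration),
         n_electrodes = as.integer(n_electrodes)),
    class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d spikes, %d electrodes, %.3f s\n",
              nrow(x$spikes), x$n_electrodes, x$duration))
  invisible(x)
}

#' Construct a stimulus train
#'
#' Ordered stimulus onset times with optional amplitude metadata. The nominal
#' period is the median successive difference (NA for a single onset).
#'
#' @param onsets strictly increasing onset times in seconds.
#' @param amplitude_mv optional stimulus amplitudes in millivolts (scalar or
#'   one per onset); metadata only.
#' @return Object of class `stimulus_train` with elements `onsets`,
#'   `amplitude_mv`, `period`.
#' @export
stimulus_train <- function(onsets, amplitude_mv = NULL) {
  onsets <- as.numeric(onsets)
  if (length(onsets) == 0L) stop("no stimuli")
  if (any(!is.finite(onsets)) || any(onsets < 0))
    stop("stimulus onsets must be finite and >= 0")
  d <- diff(onsets)
  if (any(d <= 0))
    stop(sprintf("stimulus onsets not strictly increasing at index %d",
                 which(d <= 0)[1] + 1L))
  period <- if (length(onsets) >= 2L) stats::median(d) else NA_real_
  structure(list(onsets = onsets, amplitude_mv = amplitude_mv,
                 period = period),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("<stimulus_train> %d onsets, period %s s\n",
              length(x$onsets),
              if (is.na(x$period)) "NA" else format(x$period)))
  invisible(x)
}

#' Construct a network-spike train
#'
#' Detected network spikes (NSs): transient (~100 ms) synchronized population
#' bursts. Each event carries its rate-peak time (the fiducial used for all
#' counting statistics), peak rate, and onset (first threshold crossing).
#'
#' @param peak_time_s strictly increasing peak times, seconds.
#' @param peak_rate peak network firing rate per event, spikes/ms.
#' @param onset_time_s onset time per event, seconds.
#' @param duration recording duration in seconds.
#' @return Object of class `ns_train` with elements `events` (data.frame) and
#'   `duration`.
#' @export
ns_train <- function(peak_time_s, peak_rate, onset_time_s, duration) {
  n <- length(peak_time_s)
  if (length(peak_rate) != n || length(onset_time_s) != n)
    stop("event fields must have equal length")
  if (n >= 2L && any(diff(peak_time_s) <= 0))
    stop("peak times must be strictly increasing")
  structure(
    list(events = data.frame(peak_time_s = as.numeric(peak_time_s),
                             peak_rate = as.numeric(peak_rate),
                             onset_time_s = as.numeric(onset_time_s)),
         duration = as.numeric(duration)),
    class = "ns_train")
}

#' @export
print.ns_train <- function(x, ...) {
  cat(sprintf("<ns_train> %d events over %.3f s\n",
              nrow(x$events), x$duration))
  invisible(x)
}

#' Construct a per-stimulus response table
#'
#' One row per stimulus, in stimulus order: whether a network spike followed
#' within the pairing window (`success`), the assigned NS peak time, and --
#' once computed -- latency (ms), decay duration (ms), decay censoring flag and
#' local response probability. Feature columns are NA until filled in.
#'
#' @param stim_time_s stimulus onset times, seconds.
#' @param success logical success flags.
#' @param ns_peak_time_s assigned NS peak time (NA on failure).
#' @param latency_ms,decay_ms,censored_decay,local_prob optional feature
#'   columns; default NA.
#' @return A data.frame of class `response_table`.
#' @export
response_table <- function(stim_time_s, success,
                           ns_peak_time_s = NA_real_,
                           latency_ms = NA_real_, decay_ms = NA_real_,
                           censored_decay = NA, local_prob = NA_real_) {
  n <- length(stim_time_s)
  tab <- data.frame(stim_index = seq_len(n),
                    stim_time_s = as.numeric(stim_time_s),
                    success = as.logical(success),
                    ns_peak_time_s = rep_len(as.numeric(ns_peak_time_s), n),
                    latency_ms = rep_len(as.numeric(latency_ms), n),
                    decay_ms = rep_len(as.numeric(decay_ms), n),
                    censored_decay = rep_len(as.logical(censored_decay), n),
                    local_prob = rep_len(as.numeric(local_prob), n))
  validate_response_table(tab)
  class(tab) <- c("response_table", "data.frame")
  tab
}

validate_response_table <- function(tab) {
  ok <- !is.na(tab$latency_ms)
  if (any(ok & !tab$success))
    stop("latency present for a failed response")
  lat <- tab$latency_ms[ok]
  if (any(lat <= 0 | lat > 1000))
    stop("latency must lie in (0, 1000] ms")
  lp <- tab$local_prob[!is.na(tab$local_prob)]
  if (any(lp < 0 | lp > 1)) stop("local_prob must lie in [0, 1]")
  invisible(tab)
}
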
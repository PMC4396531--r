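#' Population firing rate
#'
#' Bins all spikes, summed over electrodes, into contiguous half-open bins
#' `[k*w, (k+1)*w)` and returns the rate in spikes/ms per bin. The default
#' 3 ms bin is the resolution at which network spikes are detected.
#'
#' @param spikes a [spike_train_set()].
#' @param bin_width_ms bin width in milliseconds (default 3).
#' @return Object of class `rate_series`: list with `start` (s), `bin_width_ms`,
#'   `values` (spikes/ms per bin) and `duration` (s).
#' @export
population_rate <- function(spikes, bin_width_ms = 3) {
  stopifnot(bin_width_ms > 0)
  w <- bin_width_ms / 1000
  n_bins <- ceiling(spikes$duration / w)
  if (n_bins < 1L) n_bins <- 1L
  idx <- floor(spikes$spikes$time_s / w) + 1L
  idx[idx > n_bins] <- n_bins  # spike exactly at t = duration
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(start = 0, bin_width_ms = bin_width_ms,
                 values = counts / bin_width_ms,
                 duration = spikes$duration),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %d bins of %g ms, max %.3f spikes/ms\n",
              length(x$values), x$bin_width_ms, max(x$values, 0)))
  invisible(x)
}

#' Adaptive detection threshold
#'
#' Baseline mean + `k` standard deviations of the binned rate, computed over
#' bins outside post-stimulus windows. With sparse backgrounds on fine bins the
#' shot-noise floor of a single spike (`1/bin_width` spikes/ms) can exceed this
#' value; the returned threshold is therefore floored just above it.
#'
#' @param rate a `rate_series`.
#' @param stims optional [stimulus_train()]; bins within `window_s` after any
#'   onset are excluded from the baseline.
#' @param k number of SDs above the baseline mean (default 3).
#' @param window_s post-stimulus exclusion window in seconds (default 1).
#' @return threshold in spikes/ms.
#' @export
adaptive_threshold <- function(rate, stims = NULL, k = 3, window_s = 1) {
  w <- rate$bin_width_ms / 1000
  centers <- (seq_along(rate$values) - 0.5) * w
  keep <- rep(TRUE, length(centers))
  if (!is.null(stims)) {
    prev <- findInterval(centers, stims$onsets)
    in_win <- prev >= 1L & (centers - stims$onsets[pmax(prev, 1L)]) < window_s
    keep[in_win] <- FALSE
  }
  v <- rate$values[keep]
  max(mean(v) + k * stats::sd(v), (1 / rate$bin_width_ms) * 1.001)
}

#' Detect network spikes by rate thresholding
#'
#' A network spike is a maximal run of bins whose population rate exceeds
#' `threshold`; runs separated by less than `merge_window_ms` are merged
#' (bridging brief within-burst dips, while staying far below the 1-10 s
#' network refractory period). Per event: onset = left edge of the first
#' supra-threshold bin, peak = center of the earliest bin attaining the run
#' maximum (deterministic tie-break), peak rate = that maximum.
#'
#' @param rate a `rate_series` from [population_rate()].
#' @param threshold detection threshold, spikes/ms (strictly exceeded).
#' @param merge_window_ms merge window in ms (default 200).
#' @return An [ns_train()].
#' @export
detect_network_spikes <- function(rate, threshold = 0.15,
                                  merge_window_ms = 200) {
  stopifnot(threshold > 0, merge_window_ms >= 0)
  w <- rate$bin_width_ms / 1000
  supra <- rate$values > threshold
  if (!any(supra))
    return(ns_train(numeric(0), numeric(0), numeric(0), rate$duration))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  # merge runs whose gap (in time) is below the merge window
  if (length(run_start) > 1L) {
    gap_ms <- (run_start[-1] - run_end[-length(run_end)] - 1L) * rate$bin_width_ms
    new_event <- c(TRUE, gap_ms >= merge_window_ms)
    grp <- cumsum(new_event)
    run_start <- tapply(run_start, grp, min)
    run_end <- tapply(run_end, grp, max)
  }
  n <- length(run_start)
  onset <- peak_t <- peak_r <- numeric(n)
  for (i in seq_len(n)) {
    bins <- run_start[i]:run_end[i]
    v <- rate$values[bins]
    j <- bins[which.max(v)]          # earliest bin attaining the max
    onset[i] <- (run_start[i] - 1L) * w
    peak_t[i] <- (j - 0.5) * w
    peak_r[i] <- max(v)
  }
  ns_train(peak_t, peak_r, onset, rate$duration)
}

#' Pair network spikes with stimuli
#'
#' Stimulus i is a success iff at least one NS onset lies in
#' `[stim_i, stim_i + window_s)`; the earliest such unassigned NS is assigned
#' (earliest-stimulus wins, no reassignment). NS events assigned to no stimulus
#' are labeled spontaneous.
#'
#' @param ns an [ns_train()].
#' @param stims a [stimulus_train()].
#' @param window_s pairing window in seconds (default 1).
#' @return A [response_table()] with one row per stimulus. The attribute
#'   `assigned_ns` gives the NS row assigned to each stimulus (NA on failure);
#'   attribute `spontaneous_ns` the NS rows assigned to no stimulus.
#' @export
pair_stimuli <- function(ns, stims, window_s = 1) {
  stopifnot(window_s > 0)
  if (!is.na(stims$period) && stims$period < window_s)
    warning("stimulus period shorter than pairing window; ",
            "earliest-stimulus-wins assignment")
  onsets <- ns$events$onset_time_s
  n_stim <- length(stims$onsets)
  assigned <- rep(NA_integer_, n_stim)
  taken <- rep(FALSE, nrow(ns$events))
  j <- 1L
  for (i in seq_len(n_stim)) {
    s <- stims$onsets[i]
    while (j <= length(onsets) && onsets[j] < s) j <- j + 1L
    k <- j
    while (k <= length(onsets) && taken[k]) k <- k + 1L
    if (k <= length(onsets) && onsets[k] >= s && onsets[k] < s + window_s) {
      assigned[i] <- k
      taken[k] <- TRUE
    }
  }
  tab <- response_table(stims$onsets, !is.na(assigned),
                        ns_peak_time_s = ifelse(is.na(assigned), NA_real_,
                                                ns$events$peak_time_s[assigned]))
  attr(tab, "assigned_ns") <- assigned
  attr(tab, "spontaneous_ns") <- which(!taken)
  tab
}
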
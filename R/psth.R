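#' Centered moving average with edge truncation
#'
#' At the edges the window shrinks and the divisor is the number of bins
#' actually covered (no zero padding, which would bias peak location near
#' edges). `width` is forced to the nearest odd integer.
#'
#' @param x numeric vector.
#' @param width window width in bins.
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width %% 2L == 0L) width <- width + 1L
  if (width <= 1L) return(x)
  n <- length(x)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(0L, i - h - 1L)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Post-stimulus time histogram
#'
#' Extracts all spikes (all electrodes) in the 1500 ms following a stimulus,
#' bins them at 1 ms, and returns the raw rate together with a 5 ms
#' moving-average (used for latency) and a wider moving-average (30-100 ms,
#' used for decay duration, where it suppresses within-decay oscillations).
#'
#' @param spikes a [spike_train_set()].
#' @param stim_time_s stimulus onset, seconds.
#' @param wide_width_ms width of the wide smoothing window in ms (30-100,
#'   default 50).
#' @param window_ms extraction window (default 1500 ms).
#' @return Object of class `psth`: list with `stim_time_s`, `bin_width_ms`
#'   (1), `raw`, `smooth5`, `smooth_wide` (all spikes/ms, length
#'   `window_ms`).
#' @export
build_psth <- function(spikes, stim_time_s, wide_width_ms = 50,
                       window_ms = 1500) {
  if (wide_width_ms < 30 || wide_width_ms > 100)
    stop("wide_width_ms must lie in [30, 100] ms")
  if (stim_time_s + window_ms / 1000 > spikes$duration + 1e-9)
    stop("truncated response window: stimulus too close to recording end")
  t <- spikes$spikes$time_s  # sorted; slice by binary search
  bounds <- findInterval(c(stim_time_s - 1e-12,
                           stim_time_s + window_ms / 1000 - 1e-12), t)
  sel <- if (bounds[2] > bounds[1]) (bounds[1] + 1L):bounds[2] else integer(0)
  rel_ms <- (t[sel] - stim_time_s) * 1000
  raw <- tabulate(pmin(floor(rel_ms), window_ms - 1) + 1L,
                  nbins = window_ms)  # counts per 1 ms bin == spikes/ms
  structure(list(stim_time_s = stim_time_s, bin_width_ms = 1,
                 raw = as.numeric(raw),
                 smooth5 = moving_average(raw, 5L),
                 smooth_wide = moving_average(raw, wide_width_ms)),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> stim at %.3f s, peak smooth5 %.3f spikes/ms\n",
              x$stim_time_s, max(x$smooth5)))
  invisible(x)
}

# first local maximum of a discrete trace, with plateau handling: runs of
# equal value flanked by strictly lower values count once, at the earliest bin
local_maxima_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  left_ok <- c(TRUE, r$values[-1] > r$values[-m])
  right_ok <- c(r$values[-m] > r$values[-1], TRUE)
  starts[left_ok & right_ok]
}

#' Response latency
#'
#' Time from stimulus onset to the first maximum of the 5 ms smoothed PSTH.
#' "First maximum" is the first local maximum whose height is at least
#' `prominence_frac` times the global maximum (default 0.5); this keeps an
#' early primary peak from being displaced by a larger reverberatory second
#' peak, while `prominence_frac = "global"` selects the earliest bin attaining
#' the global maximum. Plateau ties resolve to the earliest bin.
#'
#' @param psth a [build_psth()] object.
#' @param prominence_frac fraction of the global max a local max must reach to
#'   qualify, or `"global"` for a pure argmax.
#' @return latency in ms (center of the selected 1 ms bin).
#' @export
response_latency <- function(psth, prominence_frac = 0.5) {
  v <- psth$smooth5
  gmax <- max(v)
  if (gmax <= 0) stop("no response content: all-zero smoothed PSTH")
  if (identical(prominence_frac, "global")) {
    bin <- which.max(v)
  } else {
    cand <- local_maxima_runs(v)
    cand <- cand[v[cand] >= prominence_frac * gmax]
    bin <- if (length(cand) > 0L) cand[1] else which.max(v)
  }
  (bin - 0.5) * psth$bin_width_ms
}

#' Decay duration
#'
#' Time from the PSTH first maximum (as located by [response_latency()] on the
#' 5 ms trace) to the first drop of the widely smoothed rate below
#' `rate_floor` along the falling phase. If the rate never drops below the
#' floor within the window the decay is censored at `window - latency`.
#'
#' @param psth a [build_psth()] object.
#' @param latency_ms latency previously computed for this PSTH.
#' @param rate_floor rate floor in spikes/ms (default 0.15).
#' @return list with `decay_ms` and logical `censored`.
#' @export
decay_duration <- function(psth, latency_ms, rate_floor = 0.15) {
  v <- psth$smooth_wide
  n <- length(v)
  k <- min(max(1L, as.integer(ceiling(latency_ms / psth$bin_width_ms))), n)
  if (v[k] < rate_floor) {
    message("smoothed rate already below floor at the latency bin; decay = 0")
    return(list(decay_ms = 0, censored = FALSE))
  }
  below <- which(v[k:n] < rate_floor)
  if (length(below) == 0L)
    return(list(decay_ms = n * psth$bin_width_ms - latency_ms,
                censored = TRUE))
  j <- k + below[1] - 1L
  list(decay_ms = (j - 0.5) * psth$bin_width_ms - latency_ms,
       censored = FALSE)
}

#' Local response probability
#'
#' Fraction of successes among the up-to-`2 * half_width` stimuli surrounding
#' stimulus `index` (the index stimulus itself is excluded); at the series
#' edges the window truncates and the denominator is the actual neighbor
#' count.
#'
#' @param tab a [response_table()] (or logical success vector).
#' @param index stimulus ordinal (1-based); if missing, computed for all.
#' @param half_width neighbors on each side (default 10).
#' @return fraction in `[0, 1]` (vector if `index` is missing).
#' @export
local_response_probability <- function(tab, index = NULL, half_width = 10) {
  stopifnot(half_width >= 1)
  success <- if (is.logical(tab)) tab else tab$success
  n <- length(success)
  if (n < 2L) stop("need at least 2 stimuli for local response probability")
  cs <- cumsum(c(0, success))
  calc <- function(i) {
    lo <- max(1L, i - half_width)
    hi <- min(n, i + half_width)
    ((cs[hi + 1L] - cs[lo]) - success[i]) / (hi - lo)
  }
  if (is.null(index)) vapply(seq_len(n), calc, numeric(1)) else calc(index)
}

#' Fill feature columns of a response table
#'
#' Runs [build_psth()], [response_latency()], [decay_duration()] and
#' [local_response_probability()] for every successful stimulus and writes the
#' `latency_ms`, `decay_ms`, `censored_decay` and `local_prob` columns.
#' Stimuli whose 1500 ms window would overrun the recording are left NA.
#'
#' @param spikes a [spike_train_set()].
#' @param tab a [response_table()] from [pair_stimuli()].
#' @param wide_width_ms,prominence_frac,rate_floor,half_width stage tunables,
#'   see the individual functions.
#' @return the updated [response_table()].
#' @export
add_response_features <- function(spikes, tab, wide_width_ms = 50,
                                  prominence_frac = 0.5, rate_floor = 0.15,
                                  half_width = 10) {
  for (i in which(tab$success)) {
    if (tab$stim_time_s[i] + 1.5 > spikes$duration + 1e-9) next
    p <- build_psth(spikes, tab$stim_time_s[i], wide_width_ms = wide_width_ms)
    lat <- response_latency(p, prominence_frac = prominence_frac)
    if (lat > 1000) next  # peak beyond the 1 s pairing horizon: not a paired NS peak
    dec <- decay_duration(p, lat, rate_floor = rate_floor)
    tab$latency_ms[i] <- lat
    tab$decay_ms[i] <- dec$decay_ms
    tab$censored_decay[i] <- dec$censored
  }
  tab$local_prob <- local_response_probability(tab, half_width = half_width)
  validate_response_table(tab)
  tab
}
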
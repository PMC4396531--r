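#' Serial-index autocorrelation
#'
#' Autocorrelation of a per-response series (latency or decay duration) as if
#' the responses were equally spaced: lags are counted in serial indices in
#' the stream of successful responses, not in clock time. The estimator is
#'
#'   rho(l) = sum_{i=1}^{n-l} (x_i - m)(x_{i+l} - m) / sum_{i=1}^{n} (x_i - m)^2
#'
#' with m the full-series mean and the full-length sum in the denominator
#' (Bartlett convention; guarantees rho(0) = 1 and |rho| <= 1).
#'
#' @param values numeric series, one entry per successful response, in
#'   stimulus order.
#' @param max_lag largest lag (default `min(n - 2, 200)`).
#' @return Object of class `serial_acf`: list with `lags` (0..max_lag) and
#'   `rho`.
#' @export
serial_autocorrelation <- function(values, max_lag = NULL) {
  x <- as.numeric(values)
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(n - 2L, 200L)
  if (n < max_lag + 2L) stop("series too short for requested max_lag")
  m <- mean(x)
  d <- x - m
  denom <- sum(d^2)
  if (denom == 0) stop("degenerate series: zero variance")
  rho <- vapply(0:max_lag, function(l) {
    sum(d[seq_len(n - l)] * d[seq_len(n - l) + l]) / denom
  }, numeric(1))
  structure(list(lags = 0:max_lag, rho = rho), class = "serial_acf")
}

#' @export
print.serial_acf <- function(x, ...) {
  cat(sprintf("<serial_acf> %d lags, rho(1) = %.3f\n",
              length(x$lags) - 1L, if (length(x$rho) > 1) x$rho[2] else NA))
  invisible(x)
}

#' Warped time axis for serial lags
#'
#' Converts serial-index lags to an estimate of actual time lags using the
#' average inter-response interval of the retained (successful) responses.
#'
#' @param response_times_s response times in seconds (>= 2).
#' @param lags integer lags.
#' @return seconds per lag.
#' @export
warped_time_axis <- function(response_times_s, lags) {
  if (length(response_times_s) < 2L) stop("need at least 2 response times")
  lags * mean(diff(response_times_s))
}

#' Latency-decay plane trajectory
#'
#' Orders the (latency, decay) pairs of successful responses, smooths each
#' coordinate independently with a centered edge-truncated moving average,
#' and marks consecutive non-overlapping segments of `segment_len` responses
#' (the unit in which organized vs. vagrant excursions across the plane are
#' displayed).
#'
#' @param tab a [response_table()] with features filled in.
#' @param smooth_window moving-average window in responses (odd; default 11).
#' @param segment_len segment length in responses (default 50).
#' @param drop_censored exclude censored decays (default TRUE).
#' @return Object of class `ns_trajectory`: list with `points` (data.frame
#'   latency_ms, decay_ms, response_time_s), `smoothed`, and `segments` (list
#'   of index ranges).
#' @export
build_trajectory <- function(tab, smooth_window = 11, segment_len = 50,
                             drop_censored = TRUE) {
  keep <- tab$success & !is.na(tab$latency_ms) & !is.na(tab$decay_ms)
  if (drop_censored) keep <- keep & !ifelse(is.na(tab$censored_decay), FALSE,
                                            tab$censored_decay)
  pts <- data.frame(latency_ms = tab$latency_ms[keep],
                    decay_ms = tab$decay_ms[keep],
                    response_time_s = tab$stim_time_s[keep])
  n <- nrow(pts)
  if (n < smooth_window) {
    warning("fewer responses than the smoothing window; smoothing skipped")
    sm <- pts[, c("latency_ms", "decay_ms")]
  } else {
    sm <- data.frame(latency_ms = moving_average(pts$latency_ms, smooth_window),
                     decay_ms = moving_average(pts$decay_ms, smooth_window))
  }
  n_seg <- n %/% segment_len
  segments <- lapply(seq_len(n_seg), function(k)
    ((k - 1L) * segment_len + 1L):(k * segment_len))
  structure(list(points = pts, smoothed = sm, segments = segments),
            class = "ns_trajectory")
}

#' @export
print.ns_trajectory <- function(x, ...) {
  cat(sprintf("<ns_trajectory> %d responses, %d segments\n",
              nrow(x$points), length(x$segments)))
  invisible(x)
}

#' Center of mass on the latency-decay plane
#'
#' Coordinate-wise mean of the trajectory points, by default on log10
#' coordinates (the geometric mean, matching the log-log plane on which
#' latency-decay trajectories are displayed).
#'
#' @param traj a [build_trajectory()] object.
#' @param log_plane use log10 coordinates (default TRUE).
#' @return named numeric `c(latency_ms, decay_ms)`.
#' @export
plane_center_of_mass <- function(traj, log_plane = TRUE) {
  pts <- traj$points
  if (nrow(pts) == 0L) stop("empty trajectory")
  if (log_plane) {
    c(latency_ms = 10^mean(log10(pts$latency_ms)),
      decay_ms = 10^mean(log10(pts$decay_ms)))
  } else {
    c(latency_ms = mean(pts$latency_ms), decay_ms = mean(pts$decay_ms))
  }
}

#' Write a serial ACF with warped axis
#' @param acf_obj a [serial_autocorrelation()] result.
#' @param response_times_s times of the retained responses, seconds.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_serial_acf <- function(acf_obj, response_times_s, path) {
  warped <- warped_time_axis(response_times_s, acf_obj$lags)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("lag\trho\twarped_s",
               sprintf("%d\t%.6f\t%.6f", acf_obj$lags, acf_obj$rho, warped)),
             con)
  invisible(path)
}
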
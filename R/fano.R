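#' Count sequence of a network-spike train
#'
#' Slices `[0, floor(duration/T)*T)` into non-overlapping contiguous windows of
#' `T` seconds (anchored at t = 0; the partial final window is discarded) and
#' counts NS peak times per window.
#'
#' @param ns an [ns_train()].
#' @param T_s window length in seconds.
#' @return integer vector of counts, one per complete window.
#' @export
count_sequence <- function(ns, T_s) {
  stopifnot(T_s > 0)
  n_win <- floor(ns$duration / T_s)
  if (n_win < 2) stop("T too large: fewer than 2 complete windows")
  t <- ns$events$peak_time_s
  idx <- floor(t / T_s) + 1
  idx <- idx[idx <= n_win]
  tabulate(idx, nbins = n_win)
}

#' Fano-factor curve over log-spaced window sizes
#'
#' For each window size T on a logarithmically spaced grid, computes the Fano
#' factor FF(T) = var(Z(T)) / mean(Z(T)) of the NS count sequence Z(T)
#' (sample variance, n-1 denominator). FF is 1 for a Poisson process; power-law
#' growth FF(T) ~ T^beta with beta > 0 indicates long-range correlation in NS
#' occurrence.
#'
#' @param ns an [ns_train()].
#' @param T_min,T_max grid limits in seconds (defaults 0.05 and duration/10).
#' @param points_per_decade grid density (default 20).
#' @param min_windows smallest admissible number of complete windows; T values
#'   needing fewer are dropped (default 10).
#' @return Object of class `fano_curve`: list with `T_s`, `ff`, `n_windows`.
#' @export
fano_curve <- function(ns, T_min = 0.05, T_max = NULL,
                       points_per_decade = 20, min_windows = 10) {
  if (is.null(T_max)) T_max <- ns$duration / min_windows
  stopifnot(T_min > 0, T_min < T_max)
  if (T_max > ns$duration / min_windows + 1e-9)
    stop("T_max exceeds duration/min_windows")
  n_dec <- log10(T_max / T_min)
  grid <- 10^seq(log10(T_min), log10(T_max),
                 length.out = max(2L, ceiling(n_dec * points_per_decade) + 1L))
  keep_T <- ff <- nw <- numeric(0)
  for (T_s in grid) {
    n_win <- floor(ns$duration / T_s)
    if (n_win < max(2, min_windows)) next
    z <- count_sequence(ns, T_s)
    m <- mean(z)
    if (m == 0) {
      warning(sprintf("T = %g s dropped: zero mean count", T_s))
      next
    }
    keep_T <- c(keep_T, T_s)
    ff <- c(ff, stats::var(z) / m)
    nw <- c(nw, n_win)
  }
  if (length(keep_T) < 5L)
    stop("fewer than 5 retained grid points in the Fano curve")
  structure(list(T_s = keep_T, ff = ff, n_windows = nw),
            class = "fano_curve")
}

#' @export
print.fano_curve <- function(x, ...) {
  cat(sprintf("<fano_curve> %d points, T in [%g, %g] s, FF in [%.3g, %.3g]\n",
              length(x$T_s), min(x$T_s), max(x$T_s), min(x$ff), max(x$ff)))
  invisible(x)
}

#' Interval-shuffled surrogate train
#'
#' Builds the null train used to contrast against long-range order: the
#' inter-NS intervals are permuted uniformly at random (Fisher-Yates via
#' `sample()`), preserving the first event time, the total span and the exact
#' interval multiset while destroying their serial order.
#'
#' @param ns an [ns_train()] with at least 3 events.
#' @param seed optional integer seed for reproducibility (the caller's RNG
#'   state is restored on exit).
#' @return an [ns_train()] with permuted event times (peak rates and onsets
#'   carry over in the permuted order; onset offsets follow their peaks).
#' @export
shuffle_surrogate <- function(ns, seed = NULL) {
  n <- nrow(ns$events)
  if (n < 3L) stop("need at least 3 events to shuffle intervals")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  t <- ns$events$peak_time_s
  iv <- diff(t)
  perm <- sample.int(n - 1L)
  new_t <- t[1] + c(0, cumsum(iv[perm]))
  offs <- ns$events$onset_time_s - t
  ns_train(new_t,
           ns$events$peak_rate[c(1L, perm + 1L)],
           new_t + offs[c(1L, perm + 1L)],
           ns$duration)
}

#' Fit a power law to the final rising section of a Fano curve
#'
#' Ordinary least squares of log10(FF) on log10(T). The "final rising section"
#' is delimited by the post-minimum rule: the fit starts at twice the T at
#' which FF attains its minimum and runs to the largest retained T; an
#' explicit `c(T_lo, T_hi)` overrides the rule.
#'
#' @param curve a [fano_curve()].
#' @param fit_range `"post-minimum"` (default) or numeric `c(T_lo, T_hi)` in
#'   seconds.
#' @return Object of class `powerlaw_fit`: list with `alpha`, `beta`,
#'   `fit_range`, `r2`, `n_points` (FF = alpha * T^beta).
#' @export
fit_powerlaw <- function(curve, fit_range = "post-minimum") {
  if (identical(fit_range, "post-minimum")) {
    T_lo <- 2 * curve$T_s[which.min(curve$ff)]
    T_hi <- max(curve$T_s)
  } else {
    stopifnot(is.numeric(fit_range), length(fit_range) == 2L,
              fit_range[1] < fit_range[2])
    T_lo <- fit_range[1]
    T_hi <- fit_range[2]
  }
  sel <- curve$T_s >= T_lo & curve$T_s <= T_hi
  lx <- log10(curve$T_s[sel])
  ly <- log10(curve$ff[sel])
  finite <- is.finite(ly)
  if (any(!finite)) {
    warning("non-finite FF values dropped from the power-law fit")
    lx <- lx[finite]; ly <- ly[finite]
  }
  if (length(lx) < 5L)
    stop("fewer than 5 points in the power-law fit range")
  fit <- stats::lm.fit(cbind(1, lx), ly)
  beta <- unname(fit$coefficients[2])
  alpha <- 10^unname(fit$coefficients[1])
  r2 <- if (stats::var(ly) > 0) 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2) else 1
  structure(list(alpha = alpha, beta = beta,
                 fit_range = c(T_lo = T_lo, T_hi = T_hi), r2 = r2,
                 n_points = length(lx)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> FF = %.3g * T^%.3f over [%.3g, %.3g] s (%d pts, R2 %.3f)\n",
    x$alpha, x$beta, x$fit_range[1], x$fit_range[2], x$n_points, x$r2))
  invisible(x)
}

#' Write / read a Fano curve
#' @param curve a [fano_curve()].
#' @param path file path.
#' @return `write_fano_curve` returns `path` invisibly; `read_fano_curve` a
#'   [fano_curve()].
#' @export
write_fano_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("T_s\tff\tn_windows",
               sprintf("%.6f\t%.6f\t%d", curve$T_s, curve$ff,
                       as.integer(curve$n_windows))), con)
  invisible(path)
}

#' @rdname write_fano_curve
#' @export
read_fano_curve <- function(path) {
  tl <- read_tsv_lines(path)
  header <- strsplit(tl$data[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("T_s", "ff", "n_windows")))
    stop("fano curve schema mismatch in ", path)
  df <- utils::read.table(text = tl$data[-1], sep = "\t", col.names = header)
  structure(list(T_s = df$T_s, ff = df$ff, n_windows = df$n_windows),
            class = "fano_curve")
}
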
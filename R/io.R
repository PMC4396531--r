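## Plain-text interchange: TSV with '#'-prefixed comment lines. All times are
## seconds, rates network-summed spikes/ms; persisted numerics are written at
## 1e-6 precision so write-then-read is the identity at that precision.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(all = lines, data = lines[keep], lineno = which(keep))
}

comment_override <- function(lines, key) {
  pat <- paste0("^#\\s*", key, "\\s*=\\s*([-0-9.eE+]+)\\s*$")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  as.numeric(sub(pat, "\\1", hit[1]))
}

#' Read a spike table
#'
#' Reads a tab-separated spike table with header `electrode_id<TAB>time_s`.
#' Lines starting with `#` are comments; `# duration=<s>` and
#' `# n_electrodes=<k>` override the values otherwise inferred from the data
#' (max time, max id + 1).
#'
#' @param path path to the TSV file.
#' @return A [spike_train_set()].
#' @export
read_spike_table <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$data) == 0L) stop("no spikes in ", path)
  header <- tl$data[1]
  if (!identical(strsplit(header, "\t", fixed = TRUE)[[1]][1:2],
                 c("electrode_id", "time_s")))
    stop("spike table header must be 'electrode_id\\ttime_s' in ", path)
  rows <- tl$data[-1]
  if (length(rows) == 0L) stop("no spikes in ", path)
  lineno <- tl$lineno[-1]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  id_chr <- vapply(parts, `[`, character(1), 1L)
  t_chr  <- vapply(parts, `[`, character(1), 2L)
  id <- suppressWarnings(as.numeric(id_chr))
  tt <- suppressWarnings(as.numeric(t_chr))
  bad <- which(is.na(id) | is.na(tt) | id < 0 | id != round(id) | tt < 0)
  if (length(bad) > 0L)
    stop(sprintf("parse error in %s at line %d: '%s'",
                 path, lineno[bad[1]], rows[bad[1]]))
  spike_train_set(as.integer(id), tt,
                  duration = comment_override(tl$all, "duration"),
                  n_electrodes = comment_override(tl$all, "n_electrodes"))
}

#' Write a spike table
#' @param x a [spike_train_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# duration=%.6f", x$duration),
               sprintf("# n_electrodes=%d", x$n_electrodes),
               "electrode_id\ttime_s",
               sprintf("%d\t%.6f", x$spikes$electrode_id, x$spikes$time_s)),
             con)
  invisible(path)
}

#' Read a stimulus log
#'
#' TSV with header `time_s` (optionally `time_s<TAB>amplitude_mv`). Onsets must
#' be strictly increasing; the nominal period is the median successive
#' difference (NA for a single onset).
#'
#' @param path path to the TSV file.
#' @return A [stimulus_train()].
#' @export
read_stimulus_log <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$data) < 1L) stop("empty stimulus log: ", path)
  cols <- strsplit(tl$data[1], "\t", fixed = TRUE)[[1]]
  if (cols[1] != "time_s")
    stop("stimulus log header must start with 'time_s' in ", path)
  has_amp <- length(cols) >= 2L && cols[2] == "amplitude_mv"
  rows <- tl$data[-1]
  if (length(rows) == 0L) stop("empty stimulus log: ", path)
  parts <- strsplit(rows, "\t", fixed = TRUE)
  tt <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
  if (any(is.na(tt)))
    stop(sprintf("parse error in %s at line %d", path,
                 tl$lineno[-1][which(is.na(tt))[1]]))
  amp <- if (has_amp)
    suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  stimulus_train(tt, amplitude_mv = amp)
}

#' Write a stimulus log
#' @param x a [stimulus_train()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stimulus_log <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(x$amplitude_mv)) {
    amp <- rep_len(x$amplitude_mv, length(x$onsets))
    writeLines(c("time_s\tamplitude_mv",
                 sprintf("%.6f\t%.6f", x$onsets, amp)), con)
  } else {
    writeLines(c("time_s", sprintf("%.6f", x$onsets)), con)
  }
  invisible(path)
}

fmt_na <- function(x, fmt = "%.6f") ifelse(is.na(x), "NA", sprintf(fmt, x))

#' Write / read a response table
#'
#' Tab-separated persistence of the per-stimulus [response_table()]; absent
#' values are written as `NA`. Write-then-read is the identity at 1e-6
#' precision on times and rates.
#'
#' @param tab a [response_table()].
#' @param path file path.
#' @return `write_response_table` returns `path` invisibly;
#'   `read_response_table` returns a [response_table()].
#' @export
write_response_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("stim_index", "stim_time_s", "success", "ns_peak_time_s",
                     "latency_ms", "decay_ms", "censored_decay", "local_prob",
                     sep = "\t"),
               paste(tab$stim_index,
                     sprintf("%.6f", tab$stim_time_s),
                     ifelse(tab$success, "TRUE", "FALSE"),
                     fmt_na(tab$ns_peak_time_s),
                     fmt_na(tab$latency_ms),
                     fmt_na(tab$decay_ms),
                     ifelse(is.na(tab$censored_decay), "NA",
                            ifelse(tab$censored_decay, "TRUE", "FALSE")),
                     fmt_na(tab$local_prob),
                     sep = "\t")),
             con)
  invisible(path)
}

#' @rdname write_response_table
#' @export
read_response_table <- function(path) {
  tl <- read_tsv_lines(path)
  expected <- c("stim_index", "stim_time_s", "success", "ns_peak_time_s",
                "latency_ms", "decay_ms", "censored_decay", "local_prob")
  header <- strsplit(tl$data[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected))
    stop("response table schema mismatch in ", path,
         " (missing or reordered columns)")
  df <- utils::read.table(text = tl$data[-1], sep = "\t",
                          col.names = expected, na.strings = "NA",
                          colClasses = c("integer", "numeric", "logical",
                                         "numeric", "numeric", "numeric",
                                         "logical", "numeric"))
  tab <- response_table(df$stim_time_s, df$success,
                        ns_peak_time_s = df$ns_peak_time_s,
                        latency_ms = df$latency_ms, decay_ms = df$decay_ms,
                        censored_decay = df$censored_decay,
                        local_prob = df$local_prob)
  tab$stim_index <- df$stim_index
  tab
}

#' Write / read a network-spike train
#'
#' @param ns an [ns_train()].
#' @param path file path.
#' @param assigned_stim optional integer vector (NA = spontaneous) giving the
#'   stimulus index each NS was assigned to by [pair_stimuli()].
#' @return `write_ns_train` returns `path` invisibly; `read_ns_train` an
#'   [ns_train()] (with attribute `assigned_stim` if present in the file).
#' @export
write_ns_train <- function(ns, path, assigned_stim = NULL) {
  if (is.null(assigned_stim)) assigned_stim <- attr(ns, "assigned_stim")
  if (is.null(assigned_stim))
    assigned_stim <- rep(NA_integer_, nrow(ns$events))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# duration=%.6f", ns$duration),
               "peak_time_s\tpeak_rate\tonset_time_s\tassigned_stim",
               paste(sprintf("%.6f", ns$events$peak_time_s),
                     sprintf("%.6f", ns$events$peak_rate),
                     sprintf("%.6f", ns$events$onset_time_s),
                     ifelse(is.na(assigned_stim), "NA", assigned_stim),
                     sep = "\t")),
             con)
  invisible(path)
}

#' @rdname write_ns_train
#' @export
read_ns_train <- function(path) {
  tl <- read_tsv_lines(path)
  dur <- comment_override(tl$all, "duration")
  if (is.null(dur)) stop("ns train file lacks '# duration=' in ", path)
  header <- strsplit(tl$data[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:3], c("peak_time_s", "peak_rate", "onset_time_s")))
    stop("ns train schema mismatch in ", path)
  if (length(tl$data) == 1L) {
    ns <- ns_train(numeric(0), numeric(0), numeric(0), dur)
    attr(ns, "assigned_stim") <- integer(0)
    return(ns)
  }
  df <- utils::read.table(text = tl$data[-1], sep = "\t",
                          col.names = header, na.strings = "NA")
  ns <- ns_train(df$peak_time_s, df$peak_rate, df$onset_time_s, dur)
  if ("assigned_stim" %in% header)
    attr(ns, "assigned_stim") <- as.integer(df$assigned_stim)
  ns
}
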
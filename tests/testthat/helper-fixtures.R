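# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# spike set whose 3 ms population rate is a rectangular pulse of `rate`
# spikes/ms over bins bin_lo..bin_hi (1-based), zero elsewhere
pulse_spikes <- function(bin_lo, bin_hi, rate, duration = 1, bin_ms = 3) {
  times <- unlist(lapply(bin_lo:bin_hi, function(b) {
    k <- rate * bin_ms            # spikes per bin, strictly interior offsets
    (b - 1) * bin_ms / 1000 + seq(0.05, 0.95, length.out = k) * bin_ms / 1000
  }))
  spike_train_set(rep(0L, length(times)), times, duration = duration,
                  n_electrodes = 2L)
}

# a psth object with prescribed smoothed traces (for latency/decay rules)
fake_psth <- function(smooth5, smooth_wide = smooth5) {
  structure(list(stim_time_s = 0, bin_width_ms = 1,
                 raw = smooth5, smooth5 = smooth5,
                 smooth_wide = smooth_wide),
            class = "psth")
}

ns_from_times <- function(t, duration = max(t) + 1) {
  ns_train(t, rep(1, length(t)), t, duration)
}
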
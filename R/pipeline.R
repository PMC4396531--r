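## Run orchestration: simulate -> detect -> features -> fano -> serial, driven
## by a flat key = value config file, with a machine-readable JSON manifest.

analysis_config_defaults <- function() list(
  simulate = TRUE,
  spike_table = NA_character_,       # input paths when simulate = FALSE
  stimulus_log = NA_character_,
  # generator
  sim_duration = 3600, sim_stim_rate = 1/5, sim_mode = "ou",
  sim_ff_exponent = NA_real_, sim_osc_period = NA_real_,
  sim_spontaneous = FALSE,
  # detection
  bin_ms = 3, threshold = 0.15, adaptive = FALSE, merge_ms = 200,
  pair_window_s = 1,
  # features
  wide_ms = 50, floor = 0.15, prominence = 0.5, half_width = 10,
  # fano
  tmin = 0.05, tmax = NA_real_, ppd = 20, min_windows = 10,
  fit = "auto", n_surrogates = 0,
  # serial
  max_lag = 200, smooth = 11, segment = 50, log_plane = TRUE,
  seed = 1
)

parse_config_value <- function(v) {
  v <- trimws(v)
  if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' Read a flat key = value analysis configuration
#'
#' One `key = value` pair per line; `#` starts a comment; unknown keys are
#' rejected. Missing keys take the documented stage defaults.
#'
#' @param path config file path (NULL for all defaults).
#' @return named list of class `analysis_config` (attribute `text` keeps the
#'   raw file for verbatim logging).
#' @export
read_analysis_config <- function(path = NULL) {
  cfg <- analysis_config_defaults()
  raw <- character(0)
  if (!is.null(path)) {
    raw <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", raw)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE))
        stop("malformed config line: '", ln, "'")
      key <- trimws(sub("=.*$", "", ln))
      if (!key %in% names(cfg)) stop("unknown config key: '", key, "'")
      cfg[[key]] <- parse_config_value(sub("^[^=]*=", "", ln))
    }
  }
  if (!cfg$fit %in% "auto" && !grepl("^[0-9.eE+-]+:[0-9.eE+-]+$", cfg$fit))
    stop("config 'fit' must be 'auto' or 'lo:hi'")
  structure(cfg, text = raw, class = "analysis_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), detect, features, fano and serial stages in
#' dependency order, writes every stage output under `out_dir` as TSV, and
#' returns a run manifest (also written as `manifest.json`) with the effective
#' config, file digests and collected warnings. Identical config + seed yields
#' identical output digests.
#'
#' @param config_path path to a flat key = value config file (NULL = defaults).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config_path = NULL, out_dir) {
  cfg <- read_analysis_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   stages = character(0), outputs = list(),
                   warnings = character(0))
  note <- function(w) manifest$warnings <<- c(manifest$warnings, w)
  run_stage <- function(name, expr) {
    res <- tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        note(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        manifest$stages <<- c(manifest$stages, paste0(name, ":failed"))
        write_manifest(manifest, out_dir, error = list(
          stage = name, message = conditionMessage(e)))
        stop("stage failure in '", name, "': ", conditionMessage(e),
             call. = FALSE)
      })
    manifest$stages <<- c(manifest$stages, name)
    res
  }
  out <- function(nm) file.path(out_dir, nm)

  if (isTRUE(cfg$simulate)) {
    rec <- run_stage("simulate", {
      sc <- synth_config(
        duration = cfg$sim_duration, stim_rate = cfg$sim_stim_rate,
        latent_mode = cfg$sim_mode,
        target_ff_exponent = if (is.na(cfg$sim_ff_exponent)) NULL else
          cfg$sim_ff_exponent,
        osc_period_responses = if (is.na(cfg$sim_osc_period)) NULL else
          cfg$sim_osc_period,
        spontaneous = isTRUE(cfg$sim_spontaneous), seed = cfg$seed)
      r <- generate_recording(sc)
      write_spike_table(r$spikes, out("spikes.tsv"))
      if (!is.null(r$stims)) write_stimulus_log(r$stims, out("stimuli.tsv"))
      write_truth(r$truth, out("truth.tsv"))
      r
    })
    spikes <- rec$spikes
    stims <- rec$stims
  } else {
    spikes <- run_stage("load", read_spike_table(cfg$spike_table))
    stims <- if (!is.na(cfg$stimulus_log))
      run_stage("load_stimuli", read_stimulus_log(cfg$stimulus_log))
  }

  det <- run_stage("detect", {
    rate <- population_rate(spikes, bin_width_ms = cfg$bin_ms)
    thr <- if (isTRUE(cfg$adaptive))
      adaptive_threshold(rate, stims, window_s = cfg$pair_window_s)
    else cfg$threshold
    ns <- detect_network_spikes(rate, threshold = thr,
                                merge_window_ms = cfg$merge_ms)
    tab <- NULL
    if (!is.null(stims)) {
      tab <- pair_stimuli(ns, stims, window_s = cfg$pair_window_s)
      write_ns_train(ns, out("ns_train.tsv"),
                     assigned_stim = match(seq_len(nrow(ns$events)),
                                           attr(tab, "assigned_ns")))
    } else write_ns_train(ns, out("ns_train.tsv"))
    list(ns = ns, tab = tab)
  })

  if (!is.null(det$tab)) {
    det$tab <- run_stage("features", {
      tab <- add_response_features(spikes, det$tab,
                                   wide_width_ms = cfg$wide_ms,
                                   prominence_frac = cfg$prominence,
                                   rate_floor = cfg$floor,
                                   half_width = cfg$half_width)
      write_response_table(tab, out("responses.tsv"))
      tab
    })
  }

  run_stage("fano", {
    curve <- fano_curve(det$ns, T_min = cfg$tmin,
                        T_max = if (is.na(cfg$tmax)) NULL else cfg$tmax,
                        points_per_decade = cfg$ppd,
                        min_windows = cfg$min_windows)
    fr <- if (identical(cfg$fit, "auto")) "post-minimum" else
      as.numeric(strsplit(cfg$fit, ":", fixed = TRUE)[[1]])
    fit <- fit_powerlaw(curve, fit_range = fr)
    write_fano_curve(curve, out("fano_curve.tsv"))
    writeLines(sprintf("alpha\tbeta\tT_lo\tT_hi\tr2\n%.6g\t%.6f\t%.6g\t%.6g\t%.6f",
                       fit$alpha, fit$beta, fit$fit_range[1],
                       fit$fit_range[2], fit$r2),
               out("fano_fit.tsv"))
    if (cfg$n_surrogates > 0) {
      for (s in seq_len(cfg$n_surrogates)) {
        sur <- shuffle_surrogate(det$ns, seed = cfg$seed + s)
        write_fano_curve(fano_curve(sur, T_min = cfg$tmin,
                                    T_max = if (is.na(cfg$tmax)) NULL else
                                      cfg$tmax,
                                    points_per_decade = cfg$ppd,
                                    min_windows = cfg$min_windows),
                         out(sprintf("fano_surrogate_%02d.tsv", s)))
      }
    }
    fit
  })

  if (!is.null(det$tab)) {
    run_stage("serial", {
      traj <- build_trajectory(det$tab, smooth_window = cfg$smooth,
                               segment_len = cfg$segment)
      n_resp <- nrow(traj$points)
      if (n_resp >= 4L) {
        ml <- min(cfg$max_lag, n_resp - 2L)
        write_serial_acf(
          serial_autocorrelation(traj$points$latency_ms, max_lag = ml),
          traj$points$response_time_s, out("acf_latency.tsv"))
        write_serial_acf(
          serial_autocorrelation(traj$points$decay_ms, max_lag = ml),
          traj$points$response_time_s, out("acf_decay.tsv"))
      } else note("serial: too few successful responses for autocorrelation")
      utils::write.table(
        cbind(traj$points,
              smooth_latency_ms = traj$smoothed$latency_ms,
              smooth_decay_ms = traj$smoothed$decay_ms),
        out("trajectory.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
      traj
    })
  }

  manifest <- write_manifest(manifest, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir, error = NULL) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  manifest$outputs <- digests
  if (!is.null(error)) manifest$error <- error
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  manifest
}
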
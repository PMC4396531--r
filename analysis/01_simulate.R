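#!/usr/bin/env Rscript
# Generate the demonstration recordings used by the downstream analysis
# stages: a 1 h evoked session with slowly drifting OU excitability (the
# "typical network"), written as plain-text spike/stimulus/truth tables.

suppressPackageStartupMessages(library(nsdyn))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(duration = 3600, stim_rate = 1/5, latent_mode = "ou",
                    seed = 20)
rec <- generate_recording(cfg)

write_spike_table(rec$spikes, "results/data/demo_spikes.tsv")
write_stimulus_log(rec$stims, "results/data/demo_stimuli.tsv")
write_truth(rec$truth, "results/data/demo_truth.tsv")

message(sprintf(
  "Simulated %.0f s: %d spikes on %d electrodes, %d stimuli, %d true NS (response prob %.2f)",
  cfg$duration, nrow(rec$spikes$spikes), cfg$n_electrodes,
  length(rec$stims$onsets), length(rec$truth$ns_peak_times_s),
  mean(rec$truth$per_stimulus$responded)))
message("wrote results/data/demo_{spikes,stimuli,truth}.tsv")
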
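#!/usr/bin/env Rscript
# Stage 1 — simulate the study: channel layout, reaching trials, and
# EEG epochs with the injected gamma structure (54 Hz planning burst
# over centro-parietal sensors, 66 Hz execution burst over
# parieto-occipital sensors, amplitudes scaling with target distance).
#
# Writes: results/trials.csv, results/layout.json, results/config.yaml
# Caches the heavy objects under scratch/ for the later stages.

suppressMessages(library(gammareach))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

layout <- gen_layout(24, seed = 42)
# phase-lagged coupling between parieto-occipital and centro-parietal
# sensors during execution: the long-range synchronization the wPLI/NBS
# stages are meant to detect (zero-lag burst sharing alone is invisible
# to the phase-lag index, by design)
po <- region_channels(layout, "parieto-occipital")
cp <- region_channels(layout, "centro-parietal")
coupling <- list(
  list(i = po[1], j = cp[1], lag = pi / 2, freq = 66, amp = 1.0),
  list(i = po[1], j = cp[2], lag = pi / 2, freq = 66, amp = 1.0),
  list(i = po[2], j = cp[1], lag = pi / 3, freq = 66, amp = 1.0))
cfg <- synth_config(n_subjects = 6, n_trials_per_distance = 8,
                    coupling_edges = coupling, seed = 42)
message("Layout: ", length(layout$names), " channels; regions: ",
        paste(names(table(layout$region)), table(layout$region),
              sep = "=", collapse = ", "))

reaches <- gen_reach_trials(cfg)
message("Simulated ", nrow(reaches$trials), " reaches for ",
        cfg$n_subjects, " subjects (",
        cfg$n_trials_per_distance, " per distance x 3 distances)")

epochs <- gen_eeg_epochs(reaches, layout, cfg)
message("EEG epochs: ", paste(dim(epochs$data), collapse = " x "),
        " at ", cfg$fs_eeg, " Hz, ",
        cfg$epoch_window_s[1], " to ", cfg$epoch_window_s[2],
        " s around movement onset")

write_trials_csv(reaches$trials, "results/trials.csv")
write_layout_json(layout, "results/layout.json")
write_config_yaml(cfg, "results/config.yaml")
saveRDS(list(cfg = cfg, layout = layout, reaches = reaches,
             epochs = epochs), "scratch/cohort.rds")
message("Stage 1 done.")
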
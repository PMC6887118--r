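#!/usr/bin/env Rscript
# Builds the synthetic axon-timelapse fixtures used by the downstream
# analysis scripts: noise-free validation sets (fission-prone and
# fusion-prone axons) plus one realistic noisy demonstration axon with
# actin and Drp1 channels. Fixture bundles (TIFF + truth logs) land under
# results/fixtures/.

suppressPackageStartupMessages(library(mitoaxon))

out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Rendering the demonstration axon (noisy, all channels)...")
demo_cfg <- sim_config(seed = 42, patch_rate = 0.25, drp1_rate = 0.1,
                       fission_prob_per_10min = 0.3)
demo <- simulate_dynamics(demo_cfg)
write_fixture(demo, render_stack(demo, demo_cfg),
              file.path(out, "demo_axon"))
message(sprintf("  %d fission, %d fusion events; %d patches",
                nrow(demo$fission_events), nrow(demo$fusion_events),
                nrow(demo$patches)))

message("Rendering 4 noise-free validation axons (full set is generated")
message("on the fly by 02_event_detection_validation.R)...")
for (s in 1:2) {
  cfg <- sim_config(seed = s, noise_gain = 0, noise_sd = 0,
                    fusion_prob_per_10min = 0, patch_rate = 0, drp1_rate = 0)
  tr <- simulate_dynamics(cfg)
  write_fixture(tr, render_stack(tr, cfg, channels = "mito"),
                file.path(out, sprintf("fission_axon_%02d", s)))
}
for (s in 101:102) {
  cfg <- sim_config(seed = s, noise_gain = 0, noise_sd = 0,
                    fission_prob_per_10min = 0, fusion_prob_per_10min = 1,
                    frac_moving = 0.5, frac_oscillating = 0,
                    patch_rate = 0, drp1_rate = 0)
  tr <- simulate_dynamics(cfg)
  write_fixture(tr, render_stack(tr, cfg, channels = "mito"),
                file.path(out, sprintf("fusion_axon_%02d", s - 100)))
}
message("Fixtures written to ", out)
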
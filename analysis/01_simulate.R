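#!/usr/bin/env Rscript
# Step 1: simulate one recording day on the tiltable shuttle track.
#
# The scenario follows the study conditions: three consecutive tilt blocks
# (0, 15, 25 degrees, north end elevated), about 20 laps per block at the
# published mean running speeds, a 30-unit ensemble cycling through the
# six programmed remap types, and an 8 Hz synthetic theta LFP. The session
# is written in the plain-text session format next to its ground truth.

suppressMessages(library(slopecell))

seed <- 42
cfg <- scenario_config(n_units = 30)
message("simulating session (seed ", seed, ") ...")
gs <- generate_session(cfg, seed = seed)

dir.create("results", showWarnings = FALSE)
write_session(gs$session, "results/session")
utils::write.table(gs$truth$tuning, "results/session/ground_truth_tuning.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(gs$truth$calls, "results/session/ground_truth_calls.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("wrote results/session: %d position samples, %d units, %d spikes",
                nrow(gs$session$positions), length(gs$session$spikes),
                sum(lengths(gs$session$spikes))))
message("ground truth: ",
        paste(capture.output(print(table(gs$truth$calls$true_call))),
              collapse = " "))
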
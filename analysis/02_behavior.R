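#!/usr/bin/env Rscript
# Step 2: segment the position stream into trials and apply the inclusion
# rules (complete end-to-end runs, no slower than the 7 s criterion).
# Writes the per-trial table and prints the behavioural summary that the
# downstream stages condition on.

suppressMessages(library(slopecell))

s <- load_session("results/session")
trials <- apply_trial_filters(segment_trials(s$positions, s$geometry,
                                             s$schedule))
utils::write.table(trials, "results/trials.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

inc <- trials[trials$included, ]
message(sprintf("%d trials segmented, %d included (%d incomplete, %d slow)",
                nrow(trials), nrow(inc),
                sum(trials$reason == "incomplete"),
                sum(trials$reason == "slow")))
sp <- aggregate(mean_speed_cms ~ tilt_deg + direction, inc, mean)
message("mean running speed (cm/s) by condition:")
message(paste(capture.output(print(sp, row.names = FALSE)),
              collapse = "\n"))
ext <- vapply(sort(unique(inc$tilt_deg)), function(tl)
  occupied_extent(s$positions, inc[inc$tilt_deg == tl, ], s$geometry),
  numeric(1))
message("occupied 2.5 cm bins per tilt: ",
        paste(sort(unique(inc$tilt_deg)), ext, sep = ":",
              collapse = "  "))
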
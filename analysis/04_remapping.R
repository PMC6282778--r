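#!/usr/bin/env Rscript
# Step 4: remapping. Compares the classifier's calls with the programmed
# ground truth, runs the shuffle-null spatial correlations, builds the
# sequence matrices, the elevation-half table and the split-half
# (within/between condition) control, and recomputes the contingency
# statistics on the published reference tables.

suppressMessages(library(slopecell))

s <- load_session("results/session")
truth <- utils::read.delim("results/session/ground_truth_calls.tsv")
# one full analysis with shuffle nulls serves every table in this step
# (trimmed shuffle count keeps the step interactive; the acceptance
# script runs the full 10,000)
res <- analyze_session(s, shuffles = 2000, seed = 42)

calls <- res$remap_calls
mm <- match(paste(truth$unit_id, truth$direction, truth$tilt_a,
                  truth$tilt_b),
            paste(calls$unit_id, calls$direction, calls$tilt_a,
                  calls$tilt_b))
acc <- mean(calls$call[mm] == truth$true_call)
message(sprintf("remap-call accuracy against ground truth: %.1f%%",
                100 * acc))
message(paste(capture.output(print(table(truth = truth$true_call,
                                         called = calls$call[mm]))),
              collapse = "\n"))

utils::write.table(res$correlations, "results/correlations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cc <- res$correlations
cc <- cc[!cc$skipped, ]
message(sprintf("spatial correlations: %d computed, actual > null in %.0f%%",
                nrow(cc), 100 * mean(cc$r > cc$mean_null_r, na.rm = TRUE)))

# sequence matrices, ordered by the 0-degree baseline
for (dir in c("uphill", "downhill")) {
  sm <- sequence_matrices(res, baseline_tilt = 0, direction = dir)
  for (tl in names(sm))
    utils::write.table(
      round(sm[[tl]], 4),
      sprintf("results/sequence_%s_%sdeg_by0.tsv", dir, tl),
      sep = "\t", quote = FALSE, col.names = FALSE)
}

# elevation halves and split-half control
elev <- elevation_half_table(res)
utils::write.table(as.data.frame.matrix(elev),
                   "results/elevation_half.tsv", sep = "\t",
                   quote = FALSE)
message("elevation-half table:")
message(paste(capture.output(print(elev)), collapse = "\n"))

sh <- split_half_remapping(s)
utils::write.table(sh, "results/split_half_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("split-half: stable %.0f%% within vs %.0f%% between",
                100 * mean(sh$call[sh$comparison == "within"] == "stable"),
                100 * mean(sh$call[sh$comparison == "between"] ==
                           "stable")))

# contingency statistics on the published reference tables
ref <- reference_remap_counts()
pool <- function(tab) rbind(
  remap = colSums(tab[c("turn_on", "turn_off", "field_remap",
                        "rate_remap"), ]),
  stable = tab["stable", ])
tests <- rbind(
  data.frame(test = "elevation_pooled",
             stat = chi_square_independence(pool(ref$elevation))$statistic,
             df = 1),
  data.frame(test = "elevation_3way",
             stat = chi_square_independence(rbind(
               complex = colSums(ref$elevation[c("turn_on", "turn_off",
                                                 "field_remap"), ]),
               rate = ref$elevation["rate_remap", ],
               stable = ref$elevation["stable", ]))$statistic,
             df = 2),
  data.frame(test = "stability_5way",
             stat = chi_square_independence(
               t(ref$stability[-1, ]))$statistic, df = 4),
  data.frame(test = "stability_pooled",
             stat = chi_square_independence(pool(ref$stability))$statistic,
             df = 1),
  data.frame(test = "activation_gof",
             stat = chi_square_gof(ref$activation)$statistic, df = 1))
utils::write.table(tests, "results/contingency_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("reference contingency statistics:")
message(paste(capture.output(print(tests, row.names = FALSE)),
              collapse = "\n"))
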
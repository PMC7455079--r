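#!/usr/bin/env Rscript
# Stage 3 -- healthy-control-referenced signature calls and ancestry
# frequencies.
#
# The 17 HC define a per-module normal range (mean +/- 1 SD); every patient
# score becomes +1 / 0 / -1. Per-ancestry call frequencies are tabulated
# and compared pairwise by Fisher's exact test; score distributions are
# compared by Sidak-adjusted Welch t tests.

library(slestrat)

scores_df <- utils::read.delim("results/scores.tsv", check.names = FALSE)
scores <- as.matrix(scores_df[, -1])
rownames(scores) <- scores_df$module
meta <- read_metadata("results/cohort/metadata.csv")

hc <- meta$sample_id[meta$is_control]
pat <- meta$sample_id[!meta$is_control]
nr <- fit_normal_range(scores, hc)
calls <- trichotomize(scores, nr)

utils::write.table(
  data.frame(module = rownames(calls), calls[, pat], check.names = FALSE),
  "results/calls.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

grouping <- stats::setNames(meta$ancestry, meta$sample_id)[pat]
freq <- group_frequencies(calls[, pat], grouping)
utils::write.csv(freq, "results/call_frequencies.csv", row.names = FALSE)
ft <- frequency_tests(freq)
utils::write.csv(ft, "results/frequency_tests.csv", row.names = FALSE)
wt <- pairwise_group_tests(scores[, pat], grouping, adjust = "sidak")
utils::write.csv(wt, "results/welch_tests.csv", row.names = FALSE)

sig <- ft[ft$p < 0.05, ]
cat(sprintf("%d of %d module/direction/pair contrasts differ (Fisher p < 0.05)\n",
            nrow(sig), nrow(ft)))
cat("plasma-cell call frequencies by ancestry (%):\n")
print(as.data.frame(freq[freq$module == "plasma_cell",
                         c("group", "pct_up", "pct_down")]),
      row.names = FALSE)

# how much of the module scores do clinical measures explain on their own?
lm_rows <- do.call(rbind, lapply(rownames(scores), function(m) {
  fit <- simple_linear_fit(meta$sledai[!meta$is_control], scores[m, pat])
  cbind(module = m, fit)
}))
utils::write.csv(lm_rows, "results/sledai_regressions.csv", row.names = FALSE)
cat(sprintf("max R^2 of SLEDAI vs any module score: %.3f\n",
            max(lm_rows$r_squared)))
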
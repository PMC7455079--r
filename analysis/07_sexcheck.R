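#!/usr/bin/env Rscript
# Stage 7 -- transcriptomic sex QC.
#
# The five-gene sex module score (XIST + TSIX - UTY - RPS4Y1 - USP9Y) is
# computed for every sample and compared with the recorded sex. To
# exercise the discordance report, two records are deliberately mislabeled
# before checking -- the flagged samples must be exactly those two.

library(slestrat)

expr <- read_expression("results/cohort/expression.tsv")
meta <- read_metadata("results/cohort/metadata.csv")

reported <- stats::setNames(meta$sex, meta$sample_id)
flip <- meta$sample_id[c(1L, 25L)]
reported[flip] <- "M"                      # planted mislabels

res <- sex_module_score(expr, reported = reported)
utils::write.csv(res, "results/sex_check.csv", row.names = FALSE)

disc <- res$sample[!res$concordant]
cat(sprintf("%d/%d samples concordant; discordant: %s\n",
            sum(res$concordant), nrow(res), paste(disc, collapse = ", ")))
stopifnot(setequal(disc, flip))
cat(sprintf("score range: females %.1f to %.1f\n",
            min(res$score), max(res$score)))
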
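#!/usr/bin/env Rscript
# Stage 5 -- stepwise logistic odds ratios from clinical predictors to
# signature calls.
#
# Each signature outcome (call +1, or call -1 for the "low" outcomes) is
# modeled against the 26 binary predictors after a Spearman collinearity
# screen. Entry uses the Rao score test and removal the Wald test (both at
# 0.05); models violating the Hosmer-Lemeshow calibration test are
# discarded. Retained odds ratios are mapped to interval-graph edges
# (reciprocal display for OR < 1; widths 1/5/10/20 pt).

library(slestrat)

meta <- read_metadata("results/cohort/metadata.csv")
calls_df <- utils::read.delim("results/calls.tsv", check.names = FALSE)
calls <- as.matrix(calls_df[, -1])
rownames(calls) <- calls_df$module

X <- build_predictor_matrix(meta)
screen <- spearman_screen(X)
if (length(screen$drop) > 0L) {
  cat("collinearity screen dropped:", paste(screen$drop, collapse = ", "), "\n")
} else cat("collinearity screen dropped nothing (|rho| <= 0.5 throughout)\n")
Xk <- X[, setdiff(colnames(X), screen$drop), drop = FALSE]

outcomes <- list(
  c("IGS", "high"), c("plasma_cell", "high"), c("Ig", "high"),
  c("cell_cycle", "high"), c("Treg", "high"), c("LDG", "high"),
  c("granulocyte", "high"), c("monocyte", "high"),
  c("NK_cell", "low"), c("B_cell", "low"), c("T_cytotoxic", "low"))

models <- list()
edges <- list()
for (po in outcomes) {
  nm <- paste0(po[1L], "_", po[2L])
  y <- outcome_vector(calls, po[1L], po[2L])[rownames(Xk)]
  if (sum(y) < 5L) { cat(nm, ": too few events, skipped\n"); next }
  res <- stepwise_select(y, Xk, outcome_name = nm)
  models[[nm]] <- res
  status <- if (res$discarded) "discarded (HL)" else
    sprintf("%d predictor(s)", length(res$selected))
  cat(sprintf("%-18s %s\n", nm, status))
  if (!res$discarded && !is.null(res$table)) {
    for (i in seq_len(nrow(res$table))) {
      edges[[length(edges) + 1L]] <-
        or_to_edge(res$table$term[i], nm, res$table$or[i])
    }
  }
}

jsonlite::write_json(
  lapply(models, function(m) list(
    outcome = m$outcome, selected = m$selected,
    table = if (is.null(m$table)) NULL else as.data.frame(m$table),
    hl = m$hl, discarded = m$discarded)),
  "results/stepwise.json", auto_unbox = TRUE, pretty = TRUE, digits = NA)
edges <- do.call(rbind, edges)
utils::write.csv(edges, "results/circos_edges.csv", row.names = FALSE)
cat(sprintf("%d edges written; width distribution:\n", nrow(edges)))
print(table(edges$width_pt))
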
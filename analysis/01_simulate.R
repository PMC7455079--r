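#!/usr/bin/env Rscript
# Stage 1 -- simulate the synthetic multi-ancestry SLE cohort.
#
# Two artifacts come out of this stage:
#   * a metadata-only cohort at the emulated study scale (216 AA / 1118 EA /
#     232 NAA patients + 17 HC), used for the frequency and predictor-level
#     analyses, where expression is not needed;
#   * a scored subcohort (60/120/60 + 17 HC, 2,000 genes) carrying the
#     planted ancestry/drug/serology effects, used by every expression
#     stage downstream. Sizes are chosen so the whole workflow runs in
#     minutes on one core.

library(slestrat)

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# full-scale metadata cohort
cfg_full <- cohort_config(seed = 20260101L)
meta_full <- generate_metadata(cfg_full)
utils::write.csv(meta_full, file.path(out, "metadata_full.csv"),
                 row.names = FALSE)
cat(sprintf("full metadata cohort: %d patients + %d HC\n",
            sum(!meta_full$is_control), sum(meta_full$is_control)))
grp <- autoantibody_group(meta_full[!meta_full$is_control, ])
print(round(100 * prop.table(table(meta_full$ancestry[!meta_full$is_control],
                                   grp), 1), 1))

# scored subcohort with planted effects
cfg <- cohort_config(n_per_ancestry = c(AA = 60, EA = 120, NAA = 60),
                     n_hc = 17, seed = 20260102L)
meta <- generate_metadata(cfg)
modules <- default_modules(n_genes = 2000L, seed = 20260103L)
expr <- generate_expression(meta, modules, n_genes = 2000L,
                            seed = 20260104L)
write_cohort(expr, meta, cfg, out)
write_gmt(modules, file.path(out, "modules.gmt"))
cat(sprintf("scored subcohort: %d genes x %d samples, %d modules\n",
            nrow(expr), ncol(expr), length(modules)))
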
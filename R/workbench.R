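#' Write an expression matrix as TSV
#'
#' Genes in rows, first column `gene`, then one column per sample.
#'
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(is.matrix(expr))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate an expression TSV
#'
#' Expects the layout written by [write_expression_tsv()]. Duplicate gene
#' or sample identifiers are rejected; non-numeric cells are reported with
#' their (gene, sample) coordinates.
#'
#' @param path TSV path.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  if (anyDuplicated(colnames(df))) {
    stop("duplicate sample column(s): ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "))
  }
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric cell at (", genes[bad[1L, 1L]], ", ",
         colnames(vals)[bad[1L, 2L]], "): '", vals[bad[1L, , drop = FALSE]], "'")
  }
  rownames(num) <- genes
  num
}

#' Read and validate a sample metadata CSV
#'
#' @param path CSV path with a `sample_id` column.
#' @return tibble with logical flag columns restored.
#' @export
read_metadata <- function(path) {
  # read everything as character first: an all-female cohort would
  # otherwise have its "F" sex column silently parsed as logical
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column")
  if ("sledai" %in% names(df)) df$sledai <- as.integer(df$sledai)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  flag_cols <- intersect(
    c("is_control", .autoantibody_cols, "c3_low", "c4_low", .drug_cols,
      .manifestation_cols, "age_gt50"), names(df))
  for (cl in flag_cols) df[[cl]] <- as.logical(df[[cl]])
  tibble::as_tibble(df)
}

# fan one user seed out to reproducible per-stage child seeds
.stage_seeds <- function(seed, n = 10L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir output directory.
#' @param seed global seed, fanned out to per-stage child seeds by a fixed
#'   counter scheme so stages can be rerun in isolation.
#' @param n_per_ancestry,n_hc cohort sizes.
#' @param n_genes gene universe size.
#' @param classify_genes gene count used as classifier features (module
#'   genes by default; `NULL` = all module genes).
#' @param k_folds cross-validation fold count.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       n_per_ancestry = c(AA = 60, EA = 180, NAA = 60),
                       n_hc = 17L, n_genes = 2000L, classify_genes = NULL,
                       k_folds = 10L) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_per_ancestry = n_per_ancestry, n_hc = n_hc,
                 n_genes = n_genes, classify_genes = classify_genes,
                 k_folds = k_folds),
            class = "run_config")
}

#' Run the whole stratification pipeline on a synthetic cohort
#'
#' Orchestrates, in order: cohort simulation, enrichment scoring,
#' normal-range calling and per-ancestry frequencies with Fisher tests,
#' differential expression (AA vs EA) with the randomized-split null
#' control, stepwise logistic odds ratios with interval-graph edges,
#' cross-validated ancestry classification, and transcriptomic sex QC.
#' Every stage writes plain-text outputs under the configured directory
#' and the run closes with a manifest (seeds, parameters, per-file
#' checksums) sufficient to verify a bit-identical rerun.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .stage_seeds(config$seed, 10L)
  paths <- character(0)
  put <- function(name) {
    p <- file.path(config$out_dir, name)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  # 1. simulate
  cfg <- cohort_config(n_per_ancestry = config$n_per_ancestry,
                       n_hc = config$n_hc, seed = seeds[1L])
  meta <- generate_metadata(cfg)
  modules <- default_modules(n_genes = config$n_genes, seed = seeds[2L])
  expr <- generate_expression(meta, modules, n_genes = config$n_genes,
                              seed = seeds[3L])
  if (!identical(sort(colnames(expr)), sort(meta$sample_id))) {
    stop("expression/metadata sample mismatch: ",
         paste(c(setdiff(colnames(expr), meta$sample_id),
                 setdiff(meta$sample_id, colnames(expr))), collapse = ", "))
  }
  write_expression_tsv(expr, put("expression.tsv"))
  utils::write.csv(meta, put("metadata.csv"), row.names = FALSE)
  write_gmt(modules, put("modules.gmt"))

  # 2. score
  scores <- enrichment_scores(expr, modules)
  utils::write.table(data.frame(module = rownames(scores), scores,
                                check.names = FALSE),
                     put("scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # 3. call against the HC normal range, tabulate and test frequencies
  hc_ids <- meta$sample_id[meta$is_control]
  nr <- fit_normal_range(scores, hc_ids)
  calls <- trichotomize(scores, nr)
  pat <- meta$sample_id[!meta$is_control]
  utils::write.table(data.frame(module = rownames(calls),
                                calls[, pat, drop = FALSE],
                                check.names = FALSE),
                     put("calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  grouping <- stats::setNames(meta$ancestry, meta$sample_id)[pat]
  freq <- group_frequencies(calls[, pat, drop = FALSE], grouping)
  utils::write.csv(freq, put("call_frequencies.csv"), row.names = FALSE)
  utils::write.csv(frequency_tests(freq), put("frequency_tests.csv"),
                   row.names = FALSE)

  # 4. DE (AA vs EA) + randomized-split null within EA
  aa <- meta$sample_id[meta$ancestry == "AA" & !meta$is_control]
  ea <- meta$sample_id[meta$ancestry == "EA" & !meta$is_control]
  de <- moderated_t_test(expr, aa, ea)
  utils::write.csv(de, put("de_AA_vs_EA.csv"), row.names = FALSE)
  null_ctrl <- randomization_control(expr, ea, seed = seeds[4L])
  jsonlite::write_json(list(n_deg_null_split = null_ctrl$n_deg),
                       put("de_null_control.json"), auto_unbox = TRUE)

  # 5. stepwise odds ratios for a representative outcome panel
  X <- build_predictor_matrix(meta)
  screen <- spearman_screen(X)
  Xk <- X[, setdiff(colnames(X), screen$drop), drop = FALSE]
  panel <- list(c("IGS", "high"), c("plasma_cell", "high"),
                c("LDG", "high"), c("NK_cell", "low"))
  edges <- list(); models <- list()
  for (po in panel) {
    y <- outcome_vector(calls[, pat, drop = FALSE], po[1L], po[2L])
    nm <- paste0(po[1L], "_", po[2L])
    res <- stepwise_select(y[rownames(Xk)], Xk, outcome_name = nm)
    models[[nm]] <- res
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
    put("stepwise.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(edges) > 0L) {
    utils::write.csv(do.call(rbind, edges), put("circos_edges.csv"),
                     row.names = FALSE)
  }

  # 6. ancestry classification on module genes (AA vs EA)
  feat <- intersect(unique(unlist(modules$modules)), rownames(expr))
  ids <- c(aa, ea)
  Xc <- t(expr[feat, ids, drop = FALSE])
  yc <- as.integer(ids %in% aa)
  folds <- stratified_kfold(yc, k = config$k_folds, seed = seeds[5L])
  report <- cross_validate(Xc, yc, folds)
  jsonlite::write_json(
    list(auc = report$auc, averaged = as.data.frame(report$averaged),
         top_predictors = as.data.frame(top_predictors(report$model, 25L))),
    put("classifier_report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  utils::write.csv(report$roc, put("roc_points.csv"), row.names = FALSE)

  # 7. transcriptomic sex QC
  sexrep <- sex_module_score(expr, stats::setNames(meta$sex, meta$sample_id))
  utils::write.csv(sexrep, put("sex_check.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("slestrat")),
    seed = config$seed,
    stage_seeds = seeds,
    parameters = list(n_per_ancestry = as.list(config$n_per_ancestry),
                      n_hc = config$n_hc, n_genes = config$n_genes,
                      k_folds = config$k_folds),
    checksums = as.list(tools::md5sum(unlist(paths))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
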
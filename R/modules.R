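#' Create a gene-module collection
#'
#' A module collection is the package's container for named gene sets (for
#' whole blood, the 34 hematopoietic cell-type and process modules). It is a
#' named list of character vectors with per-module descriptions and an
#' optional measurable-gene universe.
#'
#' @param modules named list of character vectors (gene identifiers).
#' @param descriptions optional character vector, one per module; defaults to
#'   empty strings.
#' @param universe optional character vector of all measurable genes; if
#'   given, every module gene must belong to it.
#' @return an object of class `module_collection`.
#' @export
module_collection <- function(modules, descriptions = NULL, universe = NULL) {
  if (length(modules) == 0L) stop("module collection must contain at least one module")
  nm <- names(modules)
  if (is.null(nm) || any(!nzchar(nm))) stop("every module must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate module name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(modules))
  stopifnot(length(descriptions) == length(modules))
  modules <- lapply(seq_along(modules), function(i) {
    g <- as.character(modules[[i]])
    if (length(g) == 0L) stop("module '", nm[i], "' is empty")
    if (anyDuplicated(g)) {
      warning("module '", nm[i], "' contains duplicate genes; deduplicated")
      g <- g[!duplicated(g)]
    }
    g
  })
  names(modules) <- nm
  if (!is.null(universe)) {
    missing <- setdiff(unique(unlist(modules)), universe)
    if (length(missing) > 0L) {
      stop("module genes absent from universe: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  structure(
    list(modules = modules,
         descriptions = stats::setNames(descriptions, nm),
         universe = universe),
    class = "module_collection"
  )
}

#' @export
print.module_collection <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat("module_collection with", length(x$modules), "modules,",
      length(unique(unlist(x$modules))), "distinct genes\n")
  cat("  sizes:", min(sizes), "-", max(sizes), "genes\n")
  invisible(x)
}

#' @export
length.module_collection <- function(x) length(x$modules)

#' Read gene modules from a GMT file
#'
#' GMT is the tab-separated gene-set format: one set per line, fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a GMT file.
#' @return a [module_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1L], " (", length(fields[[bad[1L]]]),
         " field(s); need name, description and >= 1 gene)")
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  names(genes) <- nms
  module_collection(genes, descriptions = desc)
}

#' Write gene modules to a GMT file
#'
#' @param collection a [module_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "module_collection"))
  lines <- vapply(names(collection$modules), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$modules[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pairwise shared-gene counts between modules
#'
#' Some overlap between whole-blood signature modules is intentional (shared
#' marker genes tie related signatures together); this matrix makes the
#' sharing explicit.
#'
#' @param collection a [module_collection()].
#' @return symmetric integer matrix; diagonal holds module sizes.
#' @export
module_overlap_matrix <- function(collection) {
  stopifnot(inherits(collection, "module_collection"))
  mods <- collection$modules
  n <- length(mods)
  out <- matrix(0L, n, n, dimnames = list(names(mods), names(mods)))
  for (i in seq_len(n)) {
    out[i, i] <- length(mods[[i]])
    if (i < n) {
      for (j in seq((i + 1L), n)) {
        ov <- length(intersect(mods[[i]], mods[[j]]))
        out[i, j] <- out[j, i] <- ov
      }
    }
  }
  out
}

#' Derive small-nucleolar-RNA-like outlier modules from PCA-overlapping patients
#'
#' Identifies the SLE patients whose global expression does not separate from
#' healthy controls on the first principal component, runs moderated-t
#' differential expression of that subset against the controls, and returns
#' the most increased and most decreased transcripts passing a stringent FDR
#' cut as two new modules. This reproduces the derivation of the "SNOR up
#' low"/"SNOR down low" sets: transcripts that distinguish the
#' HC-overlapping patient stratum from controls even though PCA groups them
#' together.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param hc_ids,sle_ids disjoint, non-empty character vectors of column
#'   names (healthy controls / patients).
#' @param n_top modules are the `n_top` most increased / decreased
#'   transcripts by log2 fold change (default 7).
#' @param fdr_cut BH FDR cut applied before ranking (default 0.005).
#' @return list with `up`, `down` (character vectors, possibly shorter than
#'   `n_top`), `selected_sle` (the HC-overlapping patient ids), and
#'   `de` (the moderated-t table for the comparison).
#' @export
derive_snor_modules <- function(expr, hc_ids, sle_ids, n_top = 7L,
                                fdr_cut = 0.005) {
  stopifnot(is.matrix(expr), length(hc_ids) > 0L, length(sle_ids) > 0L)
  if (length(intersect(hc_ids, sle_ids)) > 0L) {
    stop("hc_ids and sle_ids must be disjoint")
  }
  missing <- setdiff(c(hc_ids, sle_ids), colnames(expr))
  if (length(missing) > 0L) stop("samples absent from matrix: ",
                                 paste(missing, collapse = ", "))
  ids <- c(hc_ids, sle_ids)
  # covariance-scale PCA on centered log2 values, samples as observations
  pc <- stats::prcomp(t(expr[, ids, drop = FALSE]), center = TRUE,
                      scale. = FALSE, rank. = 1L)
  pc1 <- stats::setNames(pc$x[, 1L], ids)
  hc_range <- range(pc1[hc_ids])
  selected <- sle_ids[pc1[sle_ids] >= hc_range[1L] & pc1[sle_ids] <= hc_range[2L]]
  if (length(selected) < 2L) {
    warning("fewer than 2 SLE samples overlap the HC PC1 range; ",
            "returning empty modules")
    return(list(up = character(0), down = character(0),
                selected_sle = selected, de = NULL))
  }
  de <- moderated_t_test(expr, group1 = selected, group2 = hc_ids)
  hit <- de[de$q < fdr_cut, , drop = FALSE]
  up_pool   <- hit[hit$lfc > 0, , drop = FALSE]
  down_pool <- hit[hit$lfc < 0, , drop = FALSE]
  if (nrow(up_pool) < n_top || nrow(down_pool) < n_top) {
    warning("fewer than ", n_top, " transcripts pass FDR < ", fdr_cut,
            " in one direction; returning shorter module(s)")
  }
  up <- up_pool$gene[order(up_pool$lfc, decreasing = TRUE)]
  down <- down_pool$gene[order(down_pool$lfc)]
  list(up = utils::head(up, n_top),
       down = utils::head(down, n_top),
       selected_sle = selected,
       de = de)
}

#' Write derived modules with a provenance record
#'
#' Emits the two derived modules as GMT plus a JSON sidecar recording the
#' derivation parameters and the selected HC-overlapping samples.
#'
#' @param snor result of [derive_snor_modules()].
#' @param gmt_path,json_path output paths.
#' @param n_top,fdr_cut the parameters used (recorded in the sidecar).
#' @return `gmt_path`, invisibly.
#' @export
write_snor_modules <- function(snor, gmt_path, json_path,
                               n_top = 7L, fdr_cut = 0.005) {
  mods <- list()
  if (length(snor$up) > 0L) mods$SNOR_up <- snor$up
  if (length(snor$down) > 0L) mods$SNOR_down <- snor$down
  if (length(mods) == 0L) stop("no derived modules to write")
  write_gmt(module_collection(mods,
                              descriptions = rep("derived outlier module",
                                                 length(mods))),
            gmt_path)
  jsonlite::write_json(
    list(n_top = n_top, fdr_cut = fdr_cut,
         selected_sle = snor$selected_sle),
    json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(gmt_path)
}
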
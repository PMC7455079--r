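.sex_x_genes <- c("XIST", "TSIX")
.sex_y_genes <- c("UTY", "RPS4Y1", "USP9Y")

#' Transcriptome-based sex inference
#'
#' Sex module score per sample:
#' `XIST + TSIX - (UTY + RPS4Y1 + USP9Y)` on log2 expression. Female
#' samples score above zero, male samples below; exactly zero is reported
#' as indeterminate. When reported sexes are supplied, samples whose
#' inferred sex disagrees are flagged in a discordance report — the QC
#' step that catches mislabelled controls and patients.
#'
#' @param expr log2 expression matrix, genes x samples. Gene identifiers
#'   are matched case-insensitively; `aliases` maps nonstandard row names
#'   (e.g. probe ids) to the five gene symbols.
#' @param reported optional named character vector of reported sexes
#'   ("F"/"M") per sample id.
#' @param aliases optional named character vector, rowname -> gene symbol.
#' @return tibble: sample, score, inferred ("F"/"M"/"indeterminate"),
#'   reported, concordant.
#' @export
sex_module_score <- function(expr, reported = NULL, aliases = NULL) {
  stopifnot(is.matrix(expr))
  rn <- rownames(expr)
  symbols <- toupper(rn)
  if (!is.null(aliases)) {
    hit <- match(rn, names(aliases))
    symbols[!is.na(hit)] <- toupper(aliases[hit[!is.na(hit)]])
  }
  need <- c(.sex_x_genes, .sex_y_genes)
  idx <- match(need, symbols)
  if (anyNA(idx)) {
    stop("missing sex gene(s) in expression matrix: ",
         paste(need[is.na(idx)], collapse = ", "))
  }
  xs <- colSums(expr[idx[1:2], , drop = FALSE])
  ys <- colSums(expr[idx[3:5], , drop = FALSE])
  score <- xs - ys
  inferred <- ifelse(score > 0, "F", ifelse(score < 0, "M", "indeterminate"))
  out <- tibble::tibble(sample = colnames(expr), score = unname(score),
                        inferred = unname(inferred))
  if (!is.null(reported)) {
    out$reported <- unname(reported[out$sample])
    out$concordant <- out$inferred == out$reported
  }
  out
}
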
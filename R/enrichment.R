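#' Gene-level kernel-CDF statistics
#'
#' Nonparametric relative-expression statistic underlying single-sample
#' module scoring. For gene i and sample j,
#' \deqn{z_{ij} = \sum_k \Phi((x_{ij} - x_{ik}) / h_i)}
#' with a Gaussian kernel and per-gene bandwidth \eqn{h_i = s_i / 4}
#' (\eqn{s_i} = sample SD of gene i), the standard kernel choice for
#' continuous log2 microarray intensities. z is strictly increasing in the
#' expression value, so it carries each gene's within-cohort rank
#' information into the random walk without any distributional assumption.
#'
#' Zero-variance genes receive a floor bandwidth of 1e-8 (with a warning
#' naming them) instead of being dropped, so the gene universe is identical
#' across samples.
#'
#' @param expr numeric matrix of log2 expression, genes x samples, with
#'   dimnames; at least 2 samples.
#' @return matrix of the same shape as `expr`.
#' @export
gene_cdf_stats <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  sds <- apply(expr, 1L, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    warning("zero-variance gene(s) given floor bandwidth: ",
            paste(utils::head(rownames(expr)[zero], 5L), collapse = ", "),
            if (sum(zero) > 5L) ", ..." else "")
    sds[zero] <- 4e-8  # h = s/4 = 1e-8
  }
  h <- sds / 4
  z <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    z[i, ] <- rowSums(stats::pnorm(outer(x, x, "-") / h[i]))
  }
  z
}

# walk over one sample's ranked gene list; shared by the scorer.
# ord: gene indices in decreasing-z order; r: |N/2 - rank| in that order.
.ks_walk_score <- function(in_module_ord, r_ord, tau) {
  n <- length(in_module_ord)
  m <- sum(in_module_ord)
  rt <- r_ord^tau
  denom_in <- sum(rt[in_module_ord])
  step <- ifelse(in_module_ord, rt / denom_in, -1 / (n - m))
  walk <- cumsum(step)
  max(walk) + min(walk)
}

#' Per-sample module enrichment scores (KS-like random walk)
#'
#' For each sample, genes are ranked by their kernel-CDF statistic in
#' decreasing order (ties broken by gene identifier, lexicographically, so
#' results do not depend on input row order). With the symmetric rank
#' statistic \eqn{r_i = |N/2 - \mathrm{rank}_i|}, the walk down the ranked
#' list gains \eqn{r_i^\tau / \sum_{g \in G} r_g^\tau} at module genes and
#' loses \eqn{1/(N-m)} elsewhere. The score is the sum of the largest
#' positive and largest negative deviations of the walk from zero, which is
#' bounded in [-1, +1] by construction: +1 means the module's genes sit at
#' the extreme top of the sample's expression ranking, -1 the extreme
#' bottom, 0 no coherent displacement.
#'
#' @param stats gene-level statistic matrix from [gene_cdf_stats()].
#' @param modules a [module_collection()]. Module genes absent from the
#'   matrix are dropped with a warning; a module with no measured genes is
#'   omitted from the result (and listed in the `dropped` attribute); a
#'   module covering the whole universe is an error (the walk is undefined).
#' @param tau rank-weight exponent (default 1).
#' @param single_extreme if `TRUE`, score is the single walk deviation of
#'   largest magnitude rather than the max+min sum.
#' @return matrix modules x samples of scores in [-1, +1], with attribute
#'   `dropped` naming modules that had no measured genes.
#' @export
module_scores <- function(stats, modules, tau = 1, single_extreme = FALSE) {
  stopifnot(is.matrix(stats), inherits(modules, "module_collection"))
  genes <- rownames(stats)
  n <- length(genes)
  mods <- lapply(modules$modules, function(g) {
    idx <- match(g, genes)
    idx[!is.na(idx)]
  })
  lost <- vapply(seq_along(mods),
                 function(i) length(modules$modules[[i]]) - length(mods[[i]]),
                 integer(1))
  if (any(lost > 0L)) {
    warning("dropped ", sum(lost), " module gene(s) absent from the matrix (",
            paste(names(mods)[lost > 0L], collapse = ", "), ")")
  }
  empty <- lengths(mods) == 0L
  if (any(lengths(mods) == n)) {
    stop("module(s) covering the entire gene universe: ",
         paste(names(mods)[lengths(mods) == n], collapse = ", "))
  }
  keep <- names(mods)[!empty]
  out <- matrix(NA_real_, length(keep), ncol(stats),
                dimnames = list(keep, colnames(stats)))
  # rank positions are sample-specific; membership masks reused across samples
  member <- lapply(mods[keep], function(idx) {
    v <- logical(n); v[idx] <- TRUE; v
  })
  for (j in seq_len(ncol(stats))) {
    ord <- order(-stats[, j], genes)          # decreasing z, lexicographic ties
    r_ord <- abs(n / 2 - seq_len(n))
    for (k in seq_along(keep)) {
      in_mod <- member[[k]][ord]
      sc <- .ks_walk_score(in_mod, r_ord, tau)
      if (single_extreme) {
        rt <- r_ord^tau
        m <- sum(in_mod)
        step <- ifelse(in_mod, rt / sum(rt[in_mod]), -1 / (n - m))
        walk <- cumsum(step)
        sc <- if (max(walk) >= -min(walk)) max(walk) else min(walk)
      }
      out[k, j] <- sc
    }
  }
  if (any(empty)) {
    warning("module(s) with no measured genes omitted: ",
            paste(names(mods)[empty], collapse = ", "))
  }
  attr(out, "dropped") <- names(mods)[empty]
  out
}

#' Score an expression matrix against a module collection
#'
#' Convenience composition of [gene_cdf_stats()] and [module_scores()].
#'
#' @inheritParams gene_cdf_stats
#' @inheritParams module_scores
#' @return modules x samples score matrix in [-1, +1].
#' @export
enrichment_scores <- function(expr, modules, tau = 1, single_extreme = FALSE) {
  module_scores(gene_cdf_stats(expr), modules, tau = tau,
                single_extreme = single_extreme)
}
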
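# solve trigamma(y) = x by Newton iteration on a log scale (x > 0)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# moment-match the scaled-F model for gene variances:
# log s_g^2 ~ const + (spread from d_g and d0). Returns prior df d0 and
# prior variance s0^2 from the mean/variance of e_g = log s_g^2 adjusted
# for the chi^2 sampling moments (digamma/trigamma closed forms).
.fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Empirical-Bayes moderated two-group differential expression
#'
#' Per-gene two-sample comparison with the gene variances shrunk toward a
#' common prior. The pooled residual variance \eqn{s_g^2} (on
#' \eqn{d_g = n_1 + n_2 - 2} df) is combined with a prior
#' \eqn{(d_0, s_0^2)} estimated by moment-matching the log-variance
#' distribution (digamma/trigamma closed forms), giving the posterior
#' variance \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)} and a
#' moderated t on \eqn{d_0 + d_g} df. With thousands of genes this borrows
#' strength across genes exactly as the standard microarray moderated-t
#' machinery does.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param group1,group2 disjoint character vectors of column names, each of
#'   length >= 2. Fold changes are `group1 - group2`.
#' @param d0 optional prior df override: `0` turns shrinkage off (ordinary
#'   t), `Inf` pools to the common variance; default `NULL` estimates it.
#' @return tibble: gene, lfc, t, p, q (BH-adjusted), plus attributes `d0`
#'   and `s0_2` with the fitted prior.
#' @export
moderated_t_test <- function(expr, group1, group2, d0 = NULL) {
  stopifnot(is.matrix(expr))
  if (length(intersect(group1, group2)) > 0L) stop("groups must be disjoint")
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs >= 2 samples")
  }
  missing <- setdiff(c(group1, group2), colnames(expr))
  if (length(missing) > 0L) stop("sample(s) absent from matrix: ",
                                 paste(missing, collapse = ", "))
  x1 <- expr[, group1, drop = FALSE]
  x2 <- expr[, group2, drop = FALSE]
  n1 <- length(group1); n2 <- length(group2)
  if (all(x1 == x1[, 1L]) || all(x2 == x2[, 1L])) {
    stop("a group has constant expression for all genes")
  }
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2); v2 <- rowSums((x2 - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (v1 + v2) / dg
  prior <- if (is.null(d0)) .fit_variance_prior(s2, dg) else {
    list(d0 = d0, s0_2 = if (is.infinite(d0)) mean(s2) else mean(s2))
  }
  if (is.infinite(prior$d0)) {
    if (is.null(d0)) {
      warning("no between-gene variance spread; pooling to common variance")
    }
    s2_post <- rep(prior$s0_2, length(s2))
    df_post <- rep(Inf, length(s2))
  } else if (prior$d0 == 0) {
    s2_post <- s2
    df_post <- rep(dg, length(s2))
  } else {
    s2_post <- (prior$d0 * prior$s0_2 + dg * s2) / (prior$d0 + dg)
    df_post <- rep(prior$d0 + dg, length(s2))
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df_post)
  out <- tibble::tibble(gene = rownames(expr), lfc = m1 - m2,
                        t = tstat, p = p, q = bh_adjust(p))
  attr(out, "d0") <- prior$d0
  attr(out, "s0_2") <- prior$s0_2
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, with input
#' validation.
#'
#' @param p vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Randomized-split null control for differential expression
#'
#' Splits a (putatively homogeneous) sample set into two random balanced
#' halves and counts moderated-t discoveries at the FDR cut. A homogeneous
#' group should yield zero discoveries for the large majority of seeds;
#' a group secretly composed of distinct subtypes will not.
#'
#' @param expr log2 expression matrix.
#' @param samples character vector of >= 4 column names.
#' @param seed integer seed for the split.
#' @param fdr FDR cut (default 0.05).
#' @return list: `n_deg` (discovery count), `split` (the two halves).
#' @export
randomization_control <- function(expr, samples, seed, fdr = 0.05) {
  if (length(samples) < 4L) stop("need >= 4 samples")
  set.seed(seed)
  half <- sample(samples, floor(length(samples) / 2))
  rest <- setdiff(samples, half)
  de <- moderated_t_test(expr, half, rest)
  list(n_deg = sum(de$q < fdr), split = list(group1 = half, group2 = rest))
}

#' Fisher's-exact gene-list overlap test
#'
#' Tests whether two gene lists share more members than expected given a
#' common universe: two-sided Fisher exact p (hypergeometric) and the
#' conditional-MLE odds ratio on the 2x2 of membership in A x membership
#' in B.
#'
#' @param list_a,list_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes (non-empty).
#' @param fdr_note optional free-text note recording the FDR cut the lists
#'   were built at (e.g. 0.2 for cross-platform comparisons).
#' @return tibble: universe size, list sizes, overlap, odds ratio
#'   (conditional MLE, as returned by the exact test), p, note.
#' @export
overlap_test <- function(list_a, list_b, universe, fdr_note = NA_character_) {
  if (length(universe) == 0L) stop("universe is empty")
  if (!all(list_a %in% universe) || !all(list_b %in% universe)) {
    stop("lists must be subsets of the universe")
  }
  list_a <- unique(list_a); list_b <- unique(list_b)
  n <- length(unique(universe))
  k <- length(intersect(list_a, list_b))
  a <- length(list_a); b <- length(list_b)
  tab <- matrix(c(k, a - k, b - k, n - a - b + k), 2L, 2L)
  ft <- stats::fisher.test(tab)
  tibble::tibble(universe = n, size_a = a, size_b = b, overlap = k,
                 odds_ratio = unname(ft$estimate), p = ft$p.value,
                 note = fdr_note)
}
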
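#' Fit the healthy-control normal range
#'
#' Per-module arithmetic mean and sample SD (n-1 denominator) of the
#' healthy-control columns of a score matrix. The mean +/- 1 SD band is the
#' "normal range" against which patient scores are trichotomized.
#'
#' @param scores modules x samples score matrix.
#' @param hc_ids character vector of >= 2 healthy-control column names.
#' @param hc_sex optional label ("F"/"M") recorded with the range, so
#'   male analyses can carry male-control ranges.
#' @return object of class `normal_range`: tibble with module, mean, sd,
#'   plus `n_hc` and `hc_sex` attributes.
#' @export
fit_normal_range <- function(scores, hc_ids, hc_sex = "F") {
  stopifnot(is.matrix(scores))
  if (length(hc_ids) < 2L) stop("need at least 2 healthy controls")
  missing <- setdiff(hc_ids, colnames(scores))
  if (length(missing) > 0L) {
    stop("healthy-control sample(s) absent from scores: ",
         paste(missing, collapse = ", "))
  }
  hc <- scores[, hc_ids, drop = FALSE]
  out <- tibble::tibble(module = rownames(scores),
                        mean = unname(rowMeans(hc)),
                        sd = unname(apply(hc, 1L, stats::sd)))
  attr(out, "n_hc") <- length(hc_ids)
  attr(out, "hc_sex") <- hc_sex
  class(out) <- c("normal_range", class(out))
  out
}

#' Trichotomize scores against the normal range
#'
#' Call = +1 where score > mean + SD, -1 where score < mean - SD, else 0.
#' Scores exactly on a boundary call 0 (strict inequalities, the literal
#' reading of "greater or less than" the normal range). Missing scores
#' propagate as missing calls and are counted in the `qc` attribute.
#'
#' @param scores modules x samples score matrix.
#' @param range a [fit_normal_range()] result over the same modules.
#' @return integer matrix of {-1, 0, +1} calls (same dimnames), with a `qc`
#'   attribute giving the missing-call count.
#' @export
trichotomize <- function(scores, range) {
  stopifnot(is.matrix(scores), inherits(range, "normal_range"))
  if (!identical(sort(rownames(scores)), sort(range$module))) {
    stop("modules of scores and normal range differ")
  }
  mu <- range$mean[match(rownames(scores), range$module)]
  sdv <- range$sd[match(rownames(scores), range$module)]
  calls <- matrix(0L, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  calls[scores > mu + sdv] <- 1L
  calls[scores < mu - sdv] <- -1L
  calls[is.na(scores)] <- NA_integer_
  attr(calls, "qc") <- list(n_missing = sum(is.na(scores)))
  calls
}

#' Per-group call frequencies
#'
#' Counts and percentages of +1 and of -1 calls per module and group
#' (typically ancestry).
#'
#' @param calls matrix from [trichotomize()] (patients only).
#' @param grouping named character vector, sample id -> group.
#' @return tibble: module, group, n, n_up, n_down, pct_up, pct_down.
#' @export
group_frequencies <- function(calls, grouping) {
  stopifnot(is.matrix(calls))
  missing <- setdiff(colnames(calls), names(grouping))
  if (length(missing) > 0L) {
    stop("sample(s) without a group: ", paste(missing, collapse = ", "))
  }
  grouping <- grouping[colnames(calls)]
  groups <- unique(grouping)
  empty <- setdiff(groups, grouping)
  if (length(empty) > 0L) warning("empty group(s) excluded: ",
                                  paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(groups, function(g) {
    cols <- calls[, grouping == g, drop = FALSE]
    n <- ncol(cols)
    n_up <- unname(rowSums(cols == 1L, na.rm = TRUE))
    n_down <- unname(rowSums(cols == -1L, na.rm = TRUE))
    tibble::tibble(module = rownames(calls), group = g, n = n,
                   n_up = n_up, n_down = n_down,
                   pct_up = 100 * n_up / n, pct_down = 100 * n_down / n)
  }))
  out
}

#' Fisher exact tests on call frequencies between group pairs
#'
#' For every module, direction (+1 / -1) and unordered group pair, a
#' two-sided Fisher exact test on the 2x2 of (called, not called) x group.
#'
#' @param freq tibble from [group_frequencies()].
#' @return tibble: module, direction, group1, group2, p.
#' @export
frequency_tests <- function(freq) {
  groups <- unique(freq$group)
  if (length(groups) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  rows <- list()
  for (mod in unique(freq$module)) {
    fm <- freq[freq$module == mod, ]
    for (pr in pairs) {
      a <- fm[fm$group == pr[1L], ]
      b <- fm[fm$group == pr[2L], ]
      if (a$n == 0L || b$n == 0L) next
      for (dir in c("up", "down")) {
        ka <- a[[paste0("n_", dir)]]; kb <- b[[paste0("n_", dir)]]
        tab <- matrix(c(ka, a$n - ka, kb, b$n - kb), 2L, 2L)
        p <- stats::fisher.test(tab)$p.value
        rows[[length(rows) + 1L]] <- tibble::tibble(
          module = mod, direction = dir,
          group1 = pr[1L], group2 = pr[2L], p = p)
      }
    }
  }
  do.call(rbind, rows)
}

#' Pairwise Welch t tests on score distributions
#'
#' Welch's unequal-variance t (Welch-Satterthwaite df) per module and group
#' pair, optionally Sidak-adjusted over the pair family within each module.
#'
#' @param scores modules x samples score matrix (patients only).
#' @param grouping named character vector, sample id -> group.
#' @param adjust `"none"` or `"sidak"` (adjusted p = 1 - (1-p)^m over the
#'   m pairs tested per module).
#' @return tibble: module, group1, group2, t, df, p, p_adj.
#' @export
pairwise_group_tests <- function(scores, grouping, adjust = c("sidak", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(is.matrix(scores))
  grouping <- grouping[colnames(scores)]
  groups <- unique(grouping)
  if (length(groups) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  m <- length(pairs)
  rows <- list()
  for (mod in rownames(scores)) {
    for (pr in pairs) {
      x <- scores[mod, grouping == pr[1L]]
      y <- scores[mod, grouping == pr[2L]]
      if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 samples")
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        warning("zero variance in both groups for module ", mod,
                "; p undefined, reported as NA")
        tt <- list(statistic = c(t = if (mean(x) == mean(y)) 0 else Inf),
                   parameter = c(df = NA_real_), p.value = NA_real_)
      } else {
        tt <- stats::t.test(x, y, var.equal = FALSE)
      }
      p <- tt$p.value
      rows[[length(rows) + 1L]] <- tibble::tibble(
        module = mod, group1 = pr[1L], group2 = pr[2L],
        t = unname(tt$statistic), df = unname(tt$parameter), p = p,
        p_adj = if (adjust == "sidak") 1 - (1 - p)^m else p)
    }
  }
  do.call(rbind, rows)
}
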
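#' Serology group from the five autoantibody flags
#'
#' Maps each patient's anti-dsDNA/RNP/Sm/SSA/SSB flags to the mutually
#' exclusive serology groups used for stratification: patients positive for
#' RNP and/or dsDNA may carry Sm/SSA/SSB in any combination; patients with
#' none of RNP/dsDNA but any of Sm/SSA/SSB form their own group; patients
#' negative for all five are the reference group.
#'
#' @param metadata data frame with logical columns `rnp`, `dsdna`, `sm`,
#'   `ssa`, `ssb` (or a single-row list of the five flags).
#' @return character vector: `"RNP+dsDNA+"`, `"RNP+dsDNA-"`,
#'   `"RNP-dsDNA+"`, `"Sm/SSA/SSB"` or `"negative"`.
#' @export
autoantibody_group <- function(metadata) {
  rnp <- as.logical(metadata$rnp); dsdna <- as.logical(metadata$dsdna)
  other <- as.logical(metadata$sm) | as.logical(metadata$ssa) |
    as.logical(metadata$ssb)
  out <- rep("negative", length(rnp))
  out[!rnp & !dsdna & other] <- "Sm/SSA/SSB"
  out[!rnp & dsdna] <- "RNP-dsDNA+"
  out[rnp & !dsdna] <- "RNP+dsDNA-"
  out[rnp & dsdna] <- "RNP+dsDNA+"
  out
}

#' Build the 26-column binary predictor matrix
#'
#' The stepwise framework models each signature call against 26 binary
#' predictors: 3 ancestry indicators, 7 drugs, 5 manifestations, 6 serology
#' indicators (the four mutually exclusive autoantibody groups plus low C3
#' and low C4), age > 50, and 4 disease-duration categories.
#'
#' @param metadata patient metadata tibble (controls excluded by the
#'   caller or here via `is_control`).
#' @return integer matrix, patients x 26, rownames = sample ids.
#' @export
build_predictor_matrix <- function(metadata) {
  md <- metadata[!metadata$is_control, , drop = FALSE]
  grp <- autoantibody_group(md)
  b <- function(x) as.integer(x)
  X <- cbind(
    ancestry_AA = b(md$ancestry == "AA"),
    ancestry_EA = b(md$ancestry == "EA"),
    ancestry_NAA = b(md$ancestry == "NAA"),
    corticosteroids = b(md$corticosteroids),
    antimalarials = b(md$antimalarials),
    nsaids = b(md$nsaids),
    aza = b(md$aza),
    mtx = b(md$mtx),
    mmf = b(md$mmf),
    cyclophosphamide = b(md$cyclophosphamide),
    rash = b(md$rash),
    arthritis = b(md$arthritis),
    mucosal_ulcers = b(md$mucosal_ulcers),
    vasculitis = b(md$vasculitis),
    alopecia = b(md$alopecia),
    sero_RNPpos_dsDNApos = b(grp == "RNP+dsDNA+"),
    sero_RNPpos_dsDNAneg = b(grp == "RNP+dsDNA-"),
    sero_RNPneg_dsDNApos = b(grp == "RNP-dsDNA+"),
    sero_SmSSASSB = b(grp == "Sm/SSA/SSB"),
    c3_low = b(md$c3_low),
    c4_low = b(md$c4_low),
    age_gt50 = b(md$age_gt50),
    duration_le1y = b(md$duration_cat == "<=1y"),
    duration_1_5y = b(md$duration_cat == "1-5y"),
    duration_5_10y = b(md$duration_cat == "5-10y"),
    duration_gt10y = b(md$duration_cat == ">10y")
  )
  rownames(X) <- md$sample_id
  X
}

#' Binary outcome vector from signature calls
#'
#' For "high" outcomes the indicator is call == +1; for "low" outcomes
#' (e.g. low NK, low pDC) it is call == -1.
#'
#' @param calls matrix from [trichotomize()].
#' @param module module name.
#' @param direction `"high"` or `"low"`.
#' @return named 0/1 integer vector over the call columns.
#' @export
outcome_vector <- function(calls, module, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (!module %in% rownames(calls)) stop("unknown module: ", module)
  v <- calls[module, ]
  stats::setNames(as.integer(v == if (direction == "high") 1L else -1L),
                  colnames(calls))
}

#' Spearman collinearity screen
#'
#' Tie-corrected Spearman rank correlations between all predictor pairs;
#' for any pair with |rho| above the threshold the later-listed column is
#' flagged for removal (the screen the source analysis used to drop a
#' redundant ethnicity indicator correlated at rho = 0.54 with another).
#'
#' @param X numeric matrix or data frame of predictors (>= 2 columns).
#' @param threshold flagging threshold on |rho| (default 0.5).
#' @return list: `rho` (correlation matrix, NA where a column is
#'   constant), `drop` (character vector of flagged columns).
#' @export
spearman_screen <- function(X, threshold = 0.5) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 columns")
  const <- apply(X, 2L, function(c) stats::sd(c) == 0)
  if (any(const)) {
    warning("constant column(s), correlation undefined: ",
            paste(colnames(X)[const], collapse = ", "))
  }
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho) <- 1
  drop <- character(0)
  nm <- colnames(X)
  for (j in 2:ncol(X)) {
    for (i in 1:(j - 1L)) {
      if (!is.na(rho[i, j]) && abs(rho[i, j]) > threshold &&
          !(nm[i] %in% drop)) {
        drop <- union(drop, nm[j])
      }
    }
  }
  list(rho = rho, drop = drop)
}

#' Logistic regression fit with odds ratios and Wald intervals
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via `stats::glm`), returning odds ratios `exp(coef)` with 95% Wald
#' intervals `exp(coef +/- 1.96 SE)` and Wald p-values. Perfect separation
#' and singular designs are detected and raised as errors naming the
#' offending predictor.
#'
#' @param y 0/1 outcome vector.
#' @param X numeric matrix of predictors (may have zero columns for an
#'   intercept-only fit).
#' @return list: `fit` (the glm object), `table` (tibble of term,
#'   coefficient, se, odds ratio, CI, p), `converged`.
#' @export
logistic_fit <- function(y, X) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("outcome is constant")
  X <- as.matrix(X)
  if (ncol(X) > 0L && length(y) <= ncol(X)) stop("more predictors than samples")
  dat <- data.frame(.y = y)
  if (ncol(X) > 0L) dat <- cbind(dat, as.data.frame(X))
  form <- if (ncol(X) > 0L) {
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)),
                                          collapse = " + ")))
  } else stats::as.formula(".y ~ 1")
  fit <- suppressWarnings(
    stats::glm(form, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  if (ncol(X) > 0L && any(is.na(stats::coef(fit)))) {
    stop("singular design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  co <- summary(fit)$coefficients
  big <- abs(co[, "Estimate"]) > 15
  if (ncol(X) > 0L && any(big[-1L])) {
    stop("perfect separation suspected for predictor(s): ",
         paste(rownames(co)[-1L][big[-1L]], collapse = ", "))
  }
  est <- unname(co[, "Estimate"]); se <- unname(co[, "Std. Error"])
  tab <- tibble::tibble(
    term = gsub("`", "", rownames(co)),
    coef = est, se = se,
    or = exp(est),
    ci_lo = exp(est - 1.96 * se),
    ci_hi = exp(est + 1.96 * se),
    p = unname(co[, "Pr(>|z|)"]))
  list(fit = fit, table = tab, converged = fit$converged)
}

#' Hosmer-Lemeshow calibration test
#'
#' Decile-of-risk chi-square: samples are grouped by fitted probability
#' into `g` groups (quantile cuts; tied fitted values stay together),
#' observed and expected event counts are compared with
#' \eqn{\sum (O-E)^2 / (E (1 - E/n))} on g-2 df. Groups with zero expected
#' events or non-events are merged with a neighbor (df adjusted, with a
#' warning).
#'
#' @param y 0/1 outcomes.
#' @param fitted fitted probabilities in (0, 1).
#' @param g number of groups (default 10; must leave df >= 1).
#' @return list: statistic, df, p, table of per-group O/E.
#' @export
hosmer_lemeshow <- function(y, fitted, g = 10L) {
  stopifnot(length(y) == length(fitted))
  if (g < 3L) stop("g must be >= 3 (df = g - 2)")
  if (length(y) < g) stop("need at least g observations")
  if (any(fitted <= 0 | fitted >= 1)) stop("fitted probabilities must be in (0,1)")
  br <- unique(stats::quantile(fitted, probs = seq(0, 1, length.out = g + 1L)))
  grp <- cut(fitted, breaks = br, include.lowest = TRUE)
  obs <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  exp_g <- tapply(fitted, grp, sum)
  keep <- !is.na(n_g)
  obs <- obs[keep]; n_g <- n_g[keep]; exp_g <- exp_g[keep]
  # merge groups whose expected events or non-events vanish
  repeat {
    bad <- which(exp_g < 1e-9 | (n_g - exp_g) < 1e-9)
    if (length(bad) == 0L || length(n_g) <= 3L) break
    i <- bad[1L]
    j <- if (i == 1L) 2L else i - 1L
    obs[j] <- obs[j] + obs[i]; n_g[j] <- n_g[j] + n_g[i]
    exp_g[j] <- exp_g[j] + exp_g[i]
    obs <- obs[-i]; n_g <- n_g[-i]; exp_g <- exp_g[-i]
    warning("merged a risk group with zero expected count")
  }
  pbar <- exp_g / n_g
  denom <- n_g * pbar * (1 - pbar)
  num <- (obs - exp_g)^2
  terms <- ifelse(denom > 0, num / denom, ifelse(num > 0, Inf, 0))
  stat <- sum(terms)
  df <- length(n_g) - 2L
  if (df < 1L) {
    warning("too few informative risk groups for the Hosmer-Lemeshow test")
    return(list(statistic = NA_real_, df = df, p = NA_real_,
                table = tibble::tibble(n = as.numeric(n_g),
                                       observed = as.numeric(obs),
                                       expected = as.numeric(exp_g))))
  }
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tibble::tibble(n = as.numeric(n_g), observed = as.numeric(obs),
                              expected = as.numeric(exp_g)))
}

#' Stepwise logistic selection with Hosmer-Lemeshow gating
#'
#' SAS-style p-value stepwise: at each cycle the candidate with the
#' smallest Rao score-test p enters if below `p_enter`; then any included
#' term whose Wald p exceeds `p_remove` is removed (largest first),
#' iterated to stability. The final model is refit, the Hosmer-Lemeshow
#' test computed, and the model flagged as discarded when the calibration
#' test is violated (HL p below `hl_gate`).
#'
#' @param y 0/1 outcome vector.
#' @param X binary predictor matrix (e.g. [build_predictor_matrix()]).
#' @param p_enter,p_remove entry / stay significance levels (default 0.05).
#' @param hl_gate Hosmer-Lemeshow discard level (default 0.05).
#' @param hl_g HL group count (default 10).
#' @param outcome_name label stored in the result.
#' @param entry_test `"score"` (Rao, default) or `"lrt"`.
#' @return object of class `stepwise_result`: list with `outcome`,
#'   `selected`, `table` (OR/CI/p per selected predictor), `hl`
#'   (statistic/df/p, NA when no terms selected), `converged`, `discarded`.
#' @export
stepwise_select <- function(y, X, p_enter = 0.05, p_remove = 0.05,
                            hl_gate = 0.05, hl_g = 10L,
                            outcome_name = "outcome",
                            entry_test = c("score", "lrt")) {
  entry_test <- match.arg(entry_test)
  X <- as.matrix(X)
  dat <- data.frame(.y = as.numeric(y), as.data.frame(X), check.names = FALSE)
  selected <- character(0)
  candidates <- colnames(X)
  refit <- function(sel) {
    form <- if (length(sel) > 0L) {
      stats::as.formula(paste(".y ~", paste(sprintf("`%s`", sel),
                                            collapse = " + ")))
    } else stats::as.formula(".y ~ 1")
    suppressWarnings(stats::glm(form, data = dat, family = stats::binomial()))
  }
  fit <- refit(selected)
  visited <- character(0)
  for (cycle in seq_len(50L)) {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0L) {
      scope <- stats::as.formula(
        paste("~ . +", paste(sprintf("`%s`", pool), collapse = " + ")))
      a1 <- suppressWarnings(
        stats::add1(fit, scope = scope,
                    test = if (entry_test == "score") "Rao" else "LRT"))
      pcol <- if (entry_test == "score") "Pr(>Chi)" else "Pr(>Chi)"
      pvals <- a1[[pcol]][-1L]
      names(pvals) <- gsub("`", "", rownames(a1)[-1L])
      pvals <- pvals[is.finite(pvals)]
      if (length(pvals) > 0L && min(pvals) < p_enter) {
        selected <- c(selected, names(pvals)[which.min(pvals)])
        fit <- refit(selected)
        changed <- TRUE
      }
    }
    # backward: drop worst Wald p > p_remove, repeat. Wald p collapses
    # toward 1 for (quasi-)separated terms (Hauck-Donner), which would
    # evict a maximally informative predictor; such terms fall back to a
    # likelihood-ratio p.
    repeat {
      if (length(selected) == 0L) break
      co <- summary(fit)$coefficients
      wp <- co[-1L, "Pr(>|z|)"]
      names(wp) <- gsub("`", "", rownames(co)[-1L])
      hd <- co[-1L, "Std. Error"] > 5
      if (any(hd)) {
        d1 <- suppressWarnings(stats::drop1(fit, test = "LRT"))
        lrt_p <- stats::setNames(d1[["Pr(>Chi)"]][-1L],
                                 gsub("`", "", rownames(d1)[-1L]))
        wp[hd] <- lrt_p[names(wp)[hd]]
      }
      if (max(wp) > p_remove) {
        selected <- setdiff(selected, names(wp)[which.max(wp)])
        fit <- refit(selected)
        changed <- TRUE
      } else break
    }
    state <- paste(sort(selected), collapse = "|")
    if (!changed || state %in% visited) break
    visited <- c(visited, state)
  }
  fit <- refit(selected)
  # table built from the final fit directly (a quasi-separated but
  # retained term gets its huge CI reported rather than an error)
  tab <- if (length(selected) > 0L) {
    co <- summary(fit)$coefficients
    est <- unname(co[, "Estimate"]); se <- unname(co[, "Std. Error"])
    t <- tibble::tibble(term = gsub("`", "", rownames(co)),
                        coef = est, se = se, or = exp(est),
                        ci_lo = exp(est - 1.96 * se),
                        ci_hi = exp(est + 1.96 * se),
                        p = unname(co[, "Pr(>|z|)"]))
    t[t$term != "(Intercept)", ]
  } else NULL
  hl <- if (length(selected) > 0L) {
    fitted <- pmin(pmax(stats::fitted(fit), 1e-10), 1 - 1e-10)
    tryCatch(hosmer_lemeshow(dat$.y, fitted, g = hl_g),
             error = function(e) list(statistic = NA_real_, df = NA_integer_,
                                      p = NA_real_))
  } else list(statistic = NA_real_, df = NA_integer_, p = NA_real_)
  discarded <- is.finite(hl$p) && hl$p < hl_gate
  structure(list(outcome = outcome_name,
                 selected = selected,
                 table = tab,
                 hl = hl[c("statistic", "df", "p")],
                 converged = fit$converged,
                 discarded = discarded),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("stepwise logistic model for", x$outcome, "\n")
  if (length(x$selected) == 0L) {
    cat("  no predictor entered\n")
  } else {
    print(x$table)
    cat(sprintf("  Hosmer-Lemeshow X2 = %.2f (df %d), p = %.3g%s\n",
                x$hl$statistic, x$hl$df, x$hl$p,
                if (x$discarded) "  [DISCARDED]" else ""))
  }
  invisible(x)
}

#' Map an odds ratio to a display edge
#'
#' For interval-graph visualisation: ORs below 1 are displayed as their
#' reciprocal with negative direction; line width follows the interval
#' rule display-OR < 2 -> 1 pt, [2, 3) -> 5 pt, [3, 10) -> 10 pt,
#' >= 10 -> 20 pt.
#'
#' @param predictor,outcome edge labels.
#' @param or_value raw odds ratio (> 0).
#' @return tibble: predictor, outcome, or, display_or, direction, width_pt.
#' @export
or_to_edge <- function(predictor, outcome, or_value) {
  if (!is.finite(or_value) || or_value <= 0) stop("odds ratio must be > 0")
  disp <- if (or_value < 1) 1 / or_value else or_value
  width <- if (disp < 2) 1L else if (disp < 3) 5L else if (disp < 10) 10L else 20L
  tibble::tibble(predictor = predictor, outcome = outcome,
                 or = or_value, display_or = disp,
                 direction = if (or_value < 1) "negative" else "positive",
                 width_pt = width)
}

#' Simple linear regression of a module score on a clinical value
#'
#' Ordinary least squares of `y` on `x`, reporting slope, intercept and
#' R squared; used to quantify how much of a module score clinical
#' measures (SLEDAI, anti-dsDNA titer, C3) explain on their own.
#'
#' @param x clinical value vector (non-constant, n >= 3).
#' @param y score vector.
#' @return tibble: slope, intercept, r_squared, p (slope Wald), n.
#' @export
simple_linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p = sm$coefficients[2L, 4L],
                 n = length(x))
}
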
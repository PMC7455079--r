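#' Stratified k-fold assignment
#'
#' Partitions samples into k folds with class proportions per fold within
#' one sample of the global proportions; deterministic per seed.
#'
#' @param labels factor-like class labels.
#' @param k fold count (default 10); every class must have >= k members.
#' @param seed integer seed.
#' @return integer vector of fold indices (1..k), named by `names(labels)`
#'   when present.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop("class '", names(tab)[which.min(tab)], "' has ", min(tab),
         " samples (< k = ", k, "); use a smaller k")
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  names(fold) <- names(labels)
  fold
}

#' Elastic-net penalized logistic classifier
#'
#' Fits a logistic model minimizing mean deviance plus
#' `l1 * ||b||_1 + l2 * ||b||_2^2 / 2`, with inputs standardized internally
#' (per-gene mean 0, SD 1 on the training data). The reported coefficients
#' are on the standardized scale, so their magnitudes are comparable
#' across genes and serve as importance scores.
#'
#' @param X samples x genes numeric matrix.
#' @param y binary labels (0/1 or two-level factor).
#' @param l1_weight,l2_weight penalty weights (>= 0). Both zero gives the
#'   unpenalized maximum-likelihood fit.
#' @return object of class `classifier_model`: standardized-scale
#'   coefficients, intercept, per-gene centers/scales, penalties.
#' @export
fit_penalized_logistic <- function(X, y, l1_weight = 0.01, l2_weight = 0.01) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite values in X")
  if (l1_weight < 0 || l2_weight < 0) stop("penalties must be >= 0")
  y <- if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  lambda <- l1_weight + l2_weight
  alpha <- if (lambda > 0) l1_weight / lambda else 0
  if (lambda == 0) {
    # glmnet needs lambda > 0 for a stable path; use an effectively
    # unpenalized value
    lambda <- 1e-8
    alpha <- 0
  }
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10)
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(X)
  structure(list(coefficients = beta,
                 intercept = as.numeric(fit$a0),
                 center = center, scale = scale_,
                 l1_weight = l1_weight, l2_weight = l2_weight),
            class = "classifier_model")
}

#' Predict class probabilities from a fitted classifier
#'
#' @param object a `classifier_model`.
#' @param newdata samples x genes matrix (original scale; standardized with
#'   the training centers/scales).
#' @param ... unused.
#' @return numeric vector of probabilities for the positive class.
#' @export
predict.classifier_model <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L,
              object$scale, "/")
  stats::plogis(object$intercept + drop(Xs %*% object$coefficients))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores (ties stepped simultaneously)
#' and integrates by the trapezoid rule; numerically identical to the
#' normalized Mann-Whitney U statistic.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels (0/1 or logical); both classes required.
#' @return list: `roc` tibble (threshold, fpr, tpr), `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cumulative counts at each distinct score (ties collapse to one step)
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(l)[keep]; fp <- cumsum(1L - l)[keep]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(roc = tibble::tibble(threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Cross-validated classification report
#'
#' For each fold, the engine is trained on the remaining folds and
#' out-of-sample class probabilities are collected. The pooled
#' probabilities give the ROC curve and AUC; thresholding at 0.5 gives
#' per-fold sensitivity/specificity/accuracy which are then averaged.
#' A fold containing a single class is skipped with a warning. The model
#' refit on all samples supplies the ranked predictors.
#'
#' @param X samples x genes matrix.
#' @param y binary labels.
#' @param folds integer fold assignment from [stratified_kfold()].
#' @param engine function `(X, y) -> model` with a `predict` method
#'   returning probabilities; default elastic-net logistic.
#' @return object of class `classifier_report`: per-fold metrics, averaged
#'   metrics, pooled ROC + AUC, out-of-sample probabilities, full-data
#'   model.
#' @export
cross_validate <- function(X, y, folds,
                           engine = function(X, y)
                             fit_penalized_logistic(X, y)) {
  X <- as.matrix(X)
  y <- if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
  stopifnot(length(y) == nrow(X), length(folds) == nrow(X))
  prob <- rep(NA_real_, length(y))
  per_fold <- list()
  for (f in sort(unique(folds))) {
    test <- folds == f
    if (length(unique(y[!test])) < 2L) {
      warning("fold ", f, " leaves a single-class training set; skipped")
      next
    }
    model <- engine(X[!test, , drop = FALSE], y[!test])
    p <- predict(model, X[test, , drop = FALSE])
    prob[test] <- p
    pred <- as.integer(p > 0.5)
    tp <- sum(pred == 1L & y[test] == 1L); tn <- sum(pred == 0L & y[test] == 0L)
    fp <- sum(pred == 1L & y[test] == 0L); fn <- sum(pred == 0L & y[test] == 1L)
    per_fold[[length(per_fold) + 1L]] <- tibble::tibble(
      fold = f,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      accuracy = (tp + tn) / sum(test))
  }
  per_fold <- do.call(rbind, per_fold)
  ok <- !is.na(prob)
  roc <- roc_auc(prob[ok], y[ok])
  full_model <- engine(X, y)
  structure(list(
    per_fold = per_fold,
    averaged = tibble::tibble(
      sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
      specificity = mean(per_fold$specificity, na.rm = TRUE),
      accuracy = mean(per_fold$accuracy, na.rm = TRUE)),
    roc = roc$roc, auc = roc$auc,
    probabilities = prob, model = full_model),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("cross-validated classifier: AUC %.3f, accuracy %.3f ",
              x$auc, x$averaged$accuracy),
      sprintf("(sens %.3f, spec %.3f) over %d folds\n",
              x$averaged$sensitivity, x$averaged$specificity,
              nrow(x$per_fold)))
  invisible(x)
}

#' Top predictors by importance
#'
#' Genes ranked by the absolute value of their standardized-input
#' coefficient (the documented importance definition); ties broken
#' lexicographically by gene identifier.
#'
#' @param model a `classifier_model`.
#' @param n how many to return (default 25; capped at the gene count).
#' @return tibble: gene, coefficient, importance, rank.
#' @export
top_predictors <- function(model, n = 25L) {
  stopifnot(inherits(model, "classifier_model"))
  b <- model$coefficients
  if (n <= 0L) {
    return(tibble::tibble(gene = character(0), coefficient = numeric(0),
                          importance = numeric(0), rank = integer(0)))
  }
  ord <- order(-abs(b), names(b))
  n <- min(n, length(b))
  idx <- ord[seq_len(n)]
  tibble::tibble(gene = names(b)[idx], coefficient = unname(b[idx]),
                 importance = abs(unname(b[idx])), rank = seq_len(n))
}
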
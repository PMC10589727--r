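# Highly-variable-region selection, Horn's parallel analysis, and the
# balanced-accuracy classification contract.

#' Select highly variable regions by the chi-square residual test
#'
#' Under the fitted intercept NB model, the sum of squared Pearson
#' residuals of a region is asymptotically chi-square with n - 1 degrees of
#' freedom (n samples, one model parameter). Regions with an upper-tail
#' Benjamini-Hochberg q-value at or below `fdr` are selected: sufficiently
#' expressed regions above the mean-variance trend, with residual clipping
#' guarding against single-sample outliers.
#'
#' @param residuals regions x samples residual matrix.
#' @param fdr FDR threshold (default 0.05).
#' @return list with `statistic`, `p`, `q` (named per region) and
#'   `selected` (region ids).
#' @export
select_hvr <- function(residuals, fdr = 0.05) {
  n <- ncol(residuals)
  stat <- rowSums(residuals^2)
  p <- stats::pchisq(stat, df = n - 1, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  ids <- rownames(residuals)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(residuals)))
  list(statistic = stats::setNames(stat, ids), p = stats::setNames(p, ids),
       q = stats::setNames(q, ids), selected = ids[q <= fdr])
}

#' PCA with Horn's permutation parallel analysis
#'
#' The number of retained components is determined by comparing the real
#' PCA eigenvalues against the eigenvalues of `n_perm` datasets in which
#' each feature's values are independently permuted across samples
#' (destroying correlation, preserving marginals). Components are retained
#' from the first while the real eigenvalue exceeds every permuted
#' eigenvalue at the same rank by a relative margin (default 5%);
#' retention stops at the first failure. For data without structure the
#' real and permuted eigenvalues are exchangeable and agree to within a
#' few percent, so comparing against the permuted mean (or bare envelope)
#' would retain spurious components; genuine components exceed the
#' permutation envelope many-fold, so the margin costs no real signal
#' while keeping the null clean.
#'
#' @param x samples x features matrix.
#' @param n_perm number of permutations (default 3).
#' @param seed integer seed.
#' @param margin relative excess over the permutation envelope required
#'   to retain a component (default 0.05).
#' @return list with `n_components`, `scores` (samples x retained),
#'   `loadings`, `eigenvalues`, `perm_eigenvalues`.
#' @export
horn_pca <- function(x, n_perm = 3L, seed = 1L, margin = 0.05) {
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  kmax <- length(ev)
  perm_ev <- with_seed(stream_seed(seed, "horn"), {
    acc <- matrix(0, n_perm, kmax)
    for (b in seq_len(n_perm)) {
      xp <- apply(x, 2, sample)
      evp <- stats::prcomp(xp, center = TRUE, scale. = FALSE)$sdev^2
      acc[b, seq_along(evp)] <- evp
    }
    matrixStats::colMaxs(acc)
  })
  exceed <- ev > (1 + margin) * perm_ev
  k <- if (exceed[1]) which.min(c(exceed, FALSE)) - 1L else 0L
  k <- min(k, min(dim(x)) - 1L)
  scores <- if (k > 0L) pc$x[, seq_len(k), drop = FALSE] else
    matrix(0, nrow(x), 0L)
  loadings <- if (k > 0L) pc$rotation[, seq_len(k), drop = FALSE] else
    matrix(0, ncol(x), 0L)
  list(n_components = k, scores = scores, loadings = loadings,
       eigenvalues = ev, perm_eigenvalues = perm_ev)
}

# Stratified fold assignment, seeded; returns an integer fold per sample.
stratified_folds <- function(labels, folds, seed) {
  with_seed(stream_seed(seed, "folds"), {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
    fold
  })
}

#' Balanced accuracy of a classifier under stratified cross-validation
#'
#' Balanced accuracy is the mean per-class recall, equivalent to accuracy
#' with each sample reweighted by its class's inverse frequency. Models:
#' k-nearest neighbors or gradient boosted trees (via xgboost, with
#' balanced class weights).
#'
#' @param scores samples x components numeric matrix.
#' @param labels class labels per sample.
#' @param model "knn" or "gbt".
#' @param folds number of CV folds (default 10; reduced with a warning if a
#'   class is smaller).
#' @param k neighbors for knn.
#' @param seed integer seed.
#' @return list with `balanced_accuracy`, `per_class_recall`, `predicted`.
#' @export
classify_balanced <- function(scores, labels, model = c("knn", "gbt"),
                              folds = 10L, k = 5L, seed = 1L) {
  model <- match.arg(model)
  labels <- factor(labels)
  stopifnot(nlevels(labels) >= 2L, nrow(scores) == length(labels))
  minc <- min(table(labels))
  if (minc < folds) {
    warning("smallest class has ", minc, " samples; reducing folds")
    folds <- max(2L, minc)
  }
  fold <- stratified_folds(as.character(labels), folds, seed)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    if (model == "knn") {
      pred[te] <- class::knn(scores[tr, , drop = FALSE],
                             scores[te, , drop = FALSE],
                             labels[tr], k = min(k, sum(tr)))
    } else {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stop("model = 'gbt' requires the xgboost package")
      ytr <- as.integer(labels[tr]) - 1L
      wts <- as.numeric(1 / table(labels[tr])[labels[tr]])
      wts <- wts / mean(wts) # mean-1 scale keeps hessian sums above
                             # xgboost's min_child_weight default
      dtr <- xgboost::xgb.DMatrix(as.matrix(scores[tr, , drop = FALSE]),
                                  label = ytr, weight = wts)
      bst <- with_seed(stream_seed(seed, paste0("gbt", f)), {
        xgboost::xgb.train(
          params = list(objective = "multi:softmax",
                        num_class = nlevels(labels),
                        max_depth = 4, eta = 0.3, nthread = 1),
          data = dtr, nrounds = 50L, verbose = 0
        )
      })
      yp <- stats::predict(bst,
                           xgboost::xgb.DMatrix(
                             as.matrix(scores[te, , drop = FALSE])))
      pred[te] <- levels(labels)[yp + 1L]
    }
  }
  recall <- vapply(levels(labels), function(cl) {
    mean(pred[labels == cl] == cl)
  }, numeric(1))
  list(balanced_accuracy = mean(recall), per_class_recall = recall,
       predicted = pred)
}
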
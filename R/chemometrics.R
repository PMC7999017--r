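#' Principal component analysis of a spectrum matrix
#'
#' Column-mean-centered PCA via the singular-value route (the Gram-matrix
#' eigendecomposition is used when there are more variables than spectra;
#' the two are algebraically identical). Loadings are orthonormal and carry a
#' deterministic sign convention: the largest-magnitude element of each
#' loading is positive. Explained-variance fractions are the eigenvalues of
#' the covariance matrix over the total variance and sum to 1 for a full
#' decomposition.
#'
#' @param x Numeric matrix, one spectrum per row.
#' @return List of class `pca_model`: `center` (mean spectrum), `loadings`
#'   (variables x components), `var_fraction`, `sdev`, `scores`
#'   (spectra x components).
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("PCA needs at least 2 spectra")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  total <- sum(xc^2) / (n - 1L)
  if (p > n) {
    e <- eigen(tcrossprod(xc), symmetric = TRUE)
    keep <- which(e$values > max(e$values[1L], 0) * 1e-12)
    d <- sqrt(e$values[keep])
    u <- e$vectors[, keep, drop = FALSE]
    v <- crossprod(xc, u) %*% diag(1 / d, length(d))
  } else {
    s <- svd(xc)
    keep <- which(s$d > max(s$d[1L], 0) * 1e-12)
    d <- s$d[keep]
    u <- s$u[, keep, drop = FALSE]
    v <- s$v[, keep, drop = FALSE]
  }
  flip <- vapply(seq_len(ncol(v)), function(j) {
    sign(v[which.max(abs(v[, j])), j])
  }, 0)
  flip[flip == 0] <- 1
  v <- sweep(v, 2L, flip, `*`)
  u <- sweep(u, 2L, flip, `*`)
  scores <- u %*% diag(d, length(d))
  ev <- d^2 / (n - 1L)
  structure(list(center = ctr, loadings = v, var_fraction = ev / total,
                 sdev = sqrt(ev), scores = scores),
            class = "pca_model")
}

#' Project spectra onto a fitted PCA model
#'
#' @param model A `pca_model`.
#' @param newx Matrix (or vector) of spectra on the model's grid.
#' @param n_pcs Number of components to keep (default all).
#' @return Score matrix, spectra x components.
#' @export
project_pca <- function(model, newx, n_pcs = ncol(model$loadings)) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  n_pcs <- min(n_pcs, ncol(model$loadings))
  sweep(as.matrix(newx), 2L, model$center) %*%
    model$loadings[, seq_len(n_pcs), drop = FALSE]
}

#' Two-class Fisher linear discriminant on PC scores
#'
#' Fisher's solution for two classes: the weight vector is
#' `Sw^-1 (mu_pos - mu_neg)` with `Sw` the pooled within-class scatter, the
#' decision threshold is the midpoint of the projected class means (equal
#' priors), and the canonical variable CV1 is the projection onto the weight
#' vector. For two classes exactly one canonical axis exists. A small ridge
#' (`1e-8 x mean diagonal`) is added automatically if `Sw` is singular.
#'
#' @param scores Numeric matrix of PC scores, one spectrum per row.
#' @param labels Group label per row; exactly two classes.
#' @param positive Label of the positive class (default `"COPD"`), which
#'   projects above the threshold.
#' @param ridge Optional ridge coefficient; `NULL` (default) adds one only on
#'   singularity.
#' @return List of class `lda_model`: `weights`, `threshold`, `positive`,
#'   `negative`, `cv1` (training canonical scores), `predicted`.
#' @export
fit_lda <- function(scores, labels, positive = "COPD", ridge = NULL) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) stop("fit_lda requires exactly two classes")
  if (!positive %in% classes) positive <- classes[1L]
  negative <- setdiff(classes, positive)
  a <- scores[labels == positive, , drop = FALSE]
  b <- scores[labels == negative, , drop = FALSE]
  if (nrow(a) < 1L || nrow(b) < 1L) stop("both classes must be present")
  mu_a <- colMeans(a)
  mu_b <- colMeans(b)
  sw <- crossprod(sweep(a, 2L, mu_a)) + crossprod(sweep(b, 2L, mu_b))
  if (!is.null(ridge)) {
    sw <- sw + diag(ridge * mean(diag(sw)), ncol(sw))
  }
  w <- tryCatch(solve(sw, mu_a - mu_b), error = function(e) {
    if (is.null(ridge)) {
      solve(sw + diag(1e-8 * max(mean(diag(sw)), .Machine$double.eps),
                      ncol(sw)), mu_a - mu_b)
    } else {
      stop("within-class scatter is singular; increase `ridge`")
    }
  })
  threshold <- sum(w * (mu_a + mu_b)) / 2
  cv1 <- drop(scores %*% w)
  structure(list(weights = w, threshold = threshold, positive = positive,
                 negative = negative, cv1 = cv1,
                 predicted = ifelse(cv1 > threshold, positive, negative)),
            class = "lda_model")
}

#' @rdname fit_lda
#' @param model A fitted `lda_model`.
#' @param scores New score matrix to classify.
#' @return For `predict_lda`: list with `cv1` and `class`.
#' @export
predict_lda <- function(model, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  cv1 <- drop(as.matrix(scores) %*% model$weights)
  list(cv1 = cv1,
       class = ifelse(cv1 > model$threshold, model$positive, model$negative))
}

#' Spectrum-level leave-one-out cross-validation
#'
#' For each spectrum, the PCA and the discriminant are refitted on the
#' remaining n-1 spectra (no train/test leakage), the held-out spectrum is
#' projected and classified, and predictions are aggregated into a confusion
#' matrix. Held-out canonical scores are reported centered on each fold's
#' decision threshold so they are comparable across folds. Setting
#' `pca_outside_cv = TRUE` reproduces the variant where the PCA is fitted
#' once on all spectra (leaky; for comparison only).
#'
#' @param x Spectra-by-grid matrix (or resampled [spectrum_set()]).
#' @param labels Group label per spectrum (taken from the set when omitted).
#' @param n_pcs Number of principal components retained (default 15).
#' @param positive Positive class label (default `"COPD"`).
#' @param pca_outside_cv Fit PCA once outside the folds (default FALSE).
#' @return List of class `loocv_result`: `confusion` (named TP/FN/TN/FP),
#'   `predictions` data frame (`label`, `predicted`, `score` = threshold-
#'   centered held-out CV1), `n_pcs`, `positive`.
#' @export
loocv <- function(x, labels = NULL, n_pcs = 15L, positive = "COPD",
                  pca_outside_cv = FALSE) {
  if (inherits(x, "spectrum_set")) {
    labels <- x$meta$group
    x <- spectra_matrix(x)
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (length(labels) != n) stop("one label per spectrum required")
  if (min(table(labels)) < 2L) stop("need at least 2 spectra per class")
  pred <- character(n)
  score <- numeric(n)
  pca_full <- if (pca_outside_cv) fit_pca(x) else NULL
  for (i in seq_len(n)) {
    if (pca_outside_cv) {
      k <- min(n_pcs, ncol(pca_full$scores))
      tr <- pca_full$scores[-i, seq_len(k), drop = FALSE]
      te <- pca_full$scores[i, seq_len(k), drop = FALSE]
    } else {
      pca <- fit_pca(x[-i, , drop = FALSE])
      k <- min(n_pcs, ncol(pca$scores))
      tr <- pca$scores[, seq_len(k), drop = FALSE]
      te <- project_pca(pca, x[i, ], n_pcs = k)
    }
    if (length(unique(labels[-i])) < 2L) {
      pred[i] <- NA_character_
      score[i] <- NA_real_
      next
    }
    mdl <- fit_lda(tr, labels[-i], positive = positive)
    pr <- predict_lda(mdl, te)
    pred[i] <- pr$class
    score[i] <- pr$cv1 - mdl$threshold
  }
  neg <- setdiff(unique(labels), positive)[1L]
  cm <- c(TP = sum(labels == positive & pred == positive, na.rm = TRUE),
          FN = sum(labels == positive & pred != positive, na.rm = TRUE),
          TN = sum(labels == neg & pred == neg, na.rm = TRUE),
          FP = sum(labels == neg & pred != neg, na.rm = TRUE))
  structure(list(confusion = cm,
                 predictions = data.frame(label = labels, predicted = pred,
                                          score = score,
                                          stringsAsFactors = FALSE),
                 n_pcs = n_pcs, positive = positive),
            class = "loocv_result")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity, specificity, precision, error rate
#' (`ER = (FP + FN) / N`, so `accuracy = 1 - ER` exactly), Matthews
#' correlation coefficient (`MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)
#' (TN+FP)(TN+FN))`, defined as 0 when any marginal is zero) . Ratios with a
#' zero denominator are reported as `NA` with attribute `undefined` naming
#' them.
#'
#' @param cm Named vector or list with `TP`, `FN`, `TN`, `FP` (COPD = positive
#'   class), or a `loocv_result`.
#' @return List of class `classification_report` with the scalar metrics.
#' @export
compute_metrics <- function(cm) {
  if (inherits(cm, "loocv_result")) cm <- cm$confusion
  cm <- unlist(cm)[c("TP", "FN", "TN", "FP")]
  if (anyNA(cm)) stop("confusion matrix must contain TP, FN, TN, FP")
  if (any(cm < 0)) stop("confusion-matrix counts must be non-negative")
  tp <- cm[["TP"]]; fn <- cm[["FN"]]; tn <- cm[["TN"]]; fp <- cm[["FP"]]
  n <- tp + fn + tn + fp
  if (n == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  undefined <- character(0)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  if (is.na(sens)) undefined <- c(undefined, "sensitivity")
  if (is.na(spec)) undefined <- c(undefined, "specificity")
  if (is.na(prec)) undefined <- c(undefined, "precision")
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) 0 else {
    (tp * tn - fp * fn) / sqrt(prod(marg))
  }
  out <- list(confusion = cm,
              accuracy = (tp + tn) / n,
              sensitivity = sens, specificity = spec, precision = prec,
              error_rate = (fp + fn) / n, mcc = mcc, n = n)
  attr(out, "undefined") <- undefined
  class(out) <- "classification_report"
  out
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("Accuracy %.3f | Sensitivity %.3f | Specificity %.3f | ",
                     "Precision %.3f | ER %.3f%% | MCC %.3f (n = %d)\n"),
              x$accuracy, x$sensitivity, x$specificity, x$precision,
              100 * x$error_rate, x$mcc, x$n))
  invisible(x)
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps the decision threshold over all distinct scores, reporting the
#' (FPR, TPR) points and the trapezoidal AUC, which equals the tie-aware
#' normalized Mann-Whitney U statistic.
#'
#' @param scores Continuous classifier scores (higher = more positive).
#' @param labels Class label per score.
#' @param positive Positive class (default `"COPD"`).
#' @return List of class `roc_curve`: `points` (data frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "COPD") {
  labels <- as.character(labels)
  y <- labels == positive
  if (!any(y) || all(y)) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yo <- y[o]
  n <- length(s)
  last_of_tie <- c(s[-n] != s[-1L], TRUE)
  tp <- cumsum(yo)[last_of_tie]
  fp <- cumsum(!yo)[last_of_tie]
  tpr <- c(0, tp / sum(y))
  fpr <- c(0, fp / sum(!y))
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(threshold = c(Inf, s[last_of_tie]),
                                     fpr = fpr, tpr = tpr),
                 auc = auc, positive = positive),
            class = "roc_curve")
}

#' Hierarchical clustering of canonical variables
#'
#' Agglomerative clustering of the canonical-variable scores (Euclidean
#' distance, Ward linkage by default), cut into two clusters, with the Rand
#' index measuring agreement between the unsupervised cut and the group
#' labels.
#'
#' @param cv_scores Numeric vector or matrix of canonical scores.
#' @param labels Group label per observation.
#' @param linkage `hclust` method (default `"ward.D2"`; `"complete"` and
#'   `"average"` are sensible alternatives).
#' @param k Number of clusters for the cut (default 2).
#' @return List: `hclust` (dendrogram object), `clusters` (cut assignment),
#'   `rand` (Rand index vs `labels`).
#' @export
hcluster_cv <- function(cv_scores, labels, linkage = "ward.D2", k = 2L) {
  m <- as.matrix(cv_scores)
  if (nrow(m) < 2L) stop("need at least 2 points")
  hc <- stats::hclust(stats::dist(m), method = linkage)
  cl <- stats::cutree(hc, k = k)
  list(hclust = hc, clusters = cl, rand = rand_index(cl, labels))
}

rand_index <- function(a, b) {
  n <- length(a)
  if (n != length(b)) stop("length mismatch")
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  mean(same_a == same_b)
}

#' One-way ANOVA on canonical-variable scores
#'
#' F statistic and p-value for a between-group difference in CV1, computed
#' from the sum-of-squares definitions: `F = (SSB / (k - 1)) /
#' (SSW / (N - k))` with the p-value from the F distribution.
#'
#' @param cv_scores Numeric vector of canonical scores.
#' @param labels Group label per observation (>= 2 per group).
#' @return List: `statistic` (F), `p_value`, `df` (between, within). When
#'   the within-group variance is exactly zero, `statistic` is `NA` with
#'   attribute `degenerate = TRUE`.
#' @export
compare_cv_distributions <- function(cv_scores, labels) {
  labels <- as.character(labels)
  groups <- split(cv_scores, labels)
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 2L)) stop("need at least 2 observations per group")
  nk <- lengths(groups)
  n <- sum(nk)
  k <- length(groups)
  mu <- mean(cv_scores)
  mu_g <- vapply(groups, mean, 0)
  ssb <- sum(nk * (mu_g - mu)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df <- c(between = k - 1L, within = n - k)
  if (ssw == 0) {
    out <- list(statistic = NA_real_, p_value = NA_real_, df = df)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  f <- (ssb / df[["between"]]) / (ssw / df[["within"]])
  list(statistic = f,
       p_value = stats::pf(f, df[["between"]], df[["within"]],
                           lower.tail = FALSE),
       df = df)
}
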
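test_that("PCA handles rank-1 data and conserves variance", {
  x <- cbind(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4))
  p <- fit_pca(x)
  expect_equal(p$var_fraction[1], 1)
  expect_length(p$var_fraction, 1L)

  set.seed(1)
  y <- matrix(rnorm(20 * 6), 20, 6)
  expect_equal(sum(fit_pca(y)$var_fraction), 1)
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(2)
  x <- matrix(rnorm(20 * 50), 20, 50)
  p <- fit_pca(x)
  e <- eigen(cov(x), symmetric = TRUE)
  k <- length(p$var_fraction)
  expect_equal(p$sdev^2, e$values[seq_len(k)], tolerance = 1e-8)
  for (j in seq_len(k)) {
    v <- e$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])  # same sign convention
    expect_equal(p$loadings[, j], v, tolerance = 1e-8)
  }
  # orthonormality and full reconstruction of the centered data
  expect_equal(crossprod(p$loadings), diag(k), tolerance = 1e-8)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(p$scores %*% t(p$loadings), xc, tolerance = 1e-8)
  # tall and wide routes agree
  pw <- fit_pca(t(xc)[1:12, ])
  expect_equal(sum(pw$var_fraction), 1)
})

test_that("cumulative explained variance is nondecreasing and projection is consistent", {
  set.seed(3)
  x <- matrix(rnorm(30 * 80), 30, 80)
  p <- fit_pca(x)
  expect_true(all(diff(p$var_fraction) <= 1e-12))
  expect_true(all(diff(cumsum(p$var_fraction)) >= 0))
  expect_equal(project_pca(p, x), p$scores, tolerance = 1e-8)
})

test_that("Fisher LDA separates separable clusters and matches the closed form", {
  set.seed(4)
  a <- cbind(rnorm(30, 5), rnorm(30, 5))
  b <- cbind(rnorm(30, -5), rnorm(30, -5))
  labels <- rep(c("COPD", "CTRL"), each = 30)
  mdl <- fit_lda(rbind(a, b), labels)
  expect_equal(mdl$predicted, labels)

  # 2-D diagonal-scatter case: w proportional to Sw^-1 (mu1 - mu2)
  xs <- rbind(c(1, 0), c(-1, 0), c(3, 1), c(3, -1)) + 10
  lb <- c("CTRL", "CTRL", "COPD", "COPD")
  m2 <- fit_lda(xs, lb)
  mu_d <- colMeans(xs[3:4, ]) - colMeans(xs[1:2, ])  # c(3, 0)
  sw <- diag(c(2, 2))  # scatter: class1 x-dev (+-1)^2, class2 y-dev (+-1)^2
  w_hand <- solve(sw, mu_d)
  expect_equal(m2$weights / sqrt(sum(m2$weights^2)),
               w_hand / sqrt(sum(w_hand^2)), tolerance = 1e-10)

  # equal means: training accuracy near chance
  set.seed(5)
  z <- matrix(rnorm(400 * 4), 400, 4)
  lz <- rep(c("COPD", "CTRL"), 200)
  mz <- fit_lda(z, lz)
  expect_lt(abs(mean(mz$predicted == lz) - 0.5), 0.1)
})

test_that("LDA direction agrees with an independent reference implementation", {
  set.seed(6)
  x <- matrix(rnorm(60 * 5), 60, 5)
  x[1:30, 1] <- x[1:30, 1] + 2
  labels <- rep(c("COPD", "CTRL"), each = 30)
  ours <- fit_lda(x, labels)
  ref <- MASS::lda(x, grouping = labels)
  cosang <- sum(ours$weights * ref$scaling) /
    sqrt(sum(ours$weights^2) * sum(ref$scaling^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-8)
})

test_that("LOOCV reproduces a hand-enumerable four-spectrum case", {
  # 1-D data {0, 1 | 10, 11}: every fold keeps both classes separable and
  # every held-out point lies on its own class's side of the midpoint
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c("COPD", "COPD", "CTRL", "CTRL")
  cv <- loocv(x, labels, n_pcs = 1)
  expect_equal(cv$predictions$predicted, labels)
  expect_equal(unname(cv$confusion), c(2L, 0L, 2L, 0L))

  # move one point across the boundary: {0, 9 | 10, 11}; holding out 9,
  # training means are 0 and 10.5, midpoint 5.25, so 9 is called CTRL
  x2 <- matrix(c(0, 9, 10, 11), ncol = 1)
  cv2 <- loocv(x2, labels, n_pcs = 1)
  expect_equal(cv2$predictions$predicted[2], "CTRL")
})

test_that("LOOCV is invariant to spectrum ordering", {
  set.seed(7)
  x <- rbind(matrix(rnorm(10 * 6, 3), 10, 6), matrix(rnorm(10 * 6, -3), 10, 6))
  labels <- rep(c("COPD", "CTRL"), each = 10)
  cv <- loocv(x, labels, n_pcs = 3)
  perm <- sample(20)
  cvp <- loocv(x[perm, ], labels[perm], n_pcs = 3)
  expect_equal(cvp$predictions$predicted[order(perm)],
               cv$predictions$predicted)
})

test_that("LOOCV on permuted labels performs at chance", {
  set.seed(8)
  x <- matrix(rnorm(240 * 12), 240, 12)
  x[1:120, 1] <- x[1:120, 1] + 5          # real structure ...
  labels <- sample(rep(c("COPD", "CTRL"), 120))  # ... decoupled from labels
  cv <- loocv(x, labels, n_pcs = 5)
  acc <- compute_metrics(cv)$accuracy
  expect_gte(acc, 0.45)
  expect_lte(acc, 0.55)
})

test_that("classification metrics follow their formulas and conventions", {
  perfect <- compute_metrics(c(TP = 50, FN = 0, TN = 50, FP = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$error_rate, 0)

  # 468-spectrum set with 4 misclassifications
  m468 <- compute_metrics(c(TP = 233, FN = 2, TN = 231, FP = 2))
  expect_equal(m468$error_rate, 4 / 468)
  expect_equal(round(100 * m468$error_rate, 2), 0.85)
  expect_equal(m468$accuracy, 1 - m468$error_rate)

  m96 <- compute_metrics(c(TP = 49, FN = 1, TN = 49, FP = 1))
  expect_equal(m96$mcc, 0.96)

  # accuracy = 1 - ER for arbitrary matrices
  set.seed(9)
  for (i in 1:20) {
    cm <- as.list(setNames(sample(0:40, 4, replace = TRUE),
                           c("TP", "FN", "TN", "FP")))
    if (sum(unlist(cm)) == 0) next
    r <- compute_metrics(cm)
    expect_equal(r$accuracy, 1 - r$error_rate)
    expect_gte(r$mcc, -1); expect_lte(r$mcc, 1)
  }

  degenerate <- compute_metrics(c(TP = 0, FN = 0, TN = 10, FP = 0))
  expect_equal(degenerate$mcc, 0)
  expect_true("sensitivity" %in% attr(degenerate, "undefined"))
  expect_error(compute_metrics(c(TP = -1, FN = 0, TN = 1, FP = 0)), "negative")
})

test_that("ROC/AUC equals exhaustive pair counting and behaves at the extremes", {
  scores <- c(0.1, 0.2, 0.3, 0.25, 0.4, 0.5)
  labels <- c(rep("CTRL", 3), rep("COPD", 3))
  r <- roc_auc(scores, labels)
  # exhaustive pair counting over the 3 x 3 positive/negative pairs
  pos <- scores[labels == "COPD"]
  neg <- scores[labels == "CTRL"]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(r$auc, mean(pairs))
  expect_equal(r$auc, 8 / 9)

  perf <- roc_auc(c(1, 2, 3, 11, 12, 13), labels)
  expect_equal(perf$auc, 1)

  set.seed(10)
  null <- roc_auc(rnorm(400), sample(rep(c("COPD", "CTRL"), 200)))
  expect_lt(abs(null$auc - 0.5), 0.08)

  # tie-free symmetry: AUC(s) + AUC(-s) = 1
  s <- rnorm(50)
  l <- sample(rep(c("COPD", "CTRL"), 25))
  expect_equal(roc_auc(s, l)$auc + roc_auc(-s, l)$auc, 1)

  expect_error(roc_auc(1:5, rep("COPD", 5)), "both classes")
})

test_that("AUC agrees with an independent reference implementation", {
  set.seed(11)
  s <- rnorm(80)
  l <- sample(rep(c("COPD", "CTRL"), 40))
  ours <- roc_auc(s, l)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(response = l, predictor = s,
                                              levels = c("CTRL", "COPD"),
                                              direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("hierarchical clustering of canonical scores separates clear groups", {
  cv1 <- c(0, 0.1, 10, 10.1)
  labels <- c("CTRL", "CTRL", "COPD", "COPD")
  h <- hcluster_cv(cv1, labels)
  expect_equal(h$rand, 1)
  expect_length(unique(h$clusters[1:2]), 1L)
  expect_length(unique(h$clusters[3:4]), 1L)

  same <- hcluster_cv(rep(1, 5), rep("COPD", 5), k = 1)
  expect_true(all(same$hclust$height == 0))
})

test_that("one-way ANOVA from sums of squares matches hand arithmetic and aov", {
  expect_equal(compare_cv_distributions(c(1, 2, 3, 1, 2, 3),
                                        rep(c("a", "b"), each = 3))$statistic, 0)

  # hand case {1,2} vs {4,6}: SSB = 12.25, SSW = 2.5, F = 9.8
  r <- compare_cv_distributions(c(1, 2, 4, 6), c("a", "a", "b", "b"))
  expect_equal(r$statistic, 9.8, tolerance = 1e-10)
  fit <- stats::aov(y ~ g, data = data.frame(y = c(1, 2, 4, 6),
                                             g = c("a", "a", "b", "b")))
  expect_equal(r$statistic, summary(fit)[[1]][["F value"]][1], tolerance = 1e-10)
  expect_equal(r$p_value, summary(fit)[[1]][["Pr(>F)"]][1], tolerance = 1e-10)

  set.seed(12)
  far <- compare_cv_distributions(c(rnorm(5, 0, 1e-3), rnorm(5, 10, 1e-3)),
                                  rep(c("a", "b"), each = 5))
  expect_lt(far$p_value, 1e-6)

  deg <- compare_cv_distributions(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(is.na(deg$statistic))
  expect_true(isTRUE(attr(deg, "degenerate")))
})
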
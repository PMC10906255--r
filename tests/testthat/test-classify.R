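# Sparse diagnostic modelling: splitting, AUC, operating point,
# permutation test, PCA.

test_that("stratified split preserves ratios and is deterministic", {
  md <- data.frame(sample_id = sprintf("S%03d", 1:100),
                   group = rep(c("HC", "COPD"), c(40, 60)),
                   age = stats::rnorm(100, 65, 8),
                   sex = sample(c("M", "F"), 100, replace = TRUE))
  sp <- split_cohort(md, validation_fraction = 0.2, seed = 5)
  expect_length(sp$validation_ids, 20)
  expect_length(sp$discovery_ids, 80)
  vt <- table(md$group[md$sample_id %in% sp$validation_ids])
  expect_lte(abs(vt[["HC"]] - 8), 1)
  expect_lte(abs(vt[["COPD"]] - 12), 1)
  sp2 <- split_cohort(md, validation_fraction = 0.2, seed = 5)
  expect_identical(sp$discovery_ids, sp2$discovery_ids)
  # balance report covers age (rank-sum) and sex (chi-square)
  expect_equal(sp$balance$variable, c("age", "sex"))
  expect_equal(sp$balance$test, c("rank-sum", "chi-square"))
  expect_error(split_cohort(md, validation_fraction = 1.2), "\\(0, 1\\)")
})

test_that("rank-statistic AUC equals the pairwise concordance oracle", {
  for (rep in 1:10) {
    set.seed(rep)
    n <- sample(10:50, 1)
    labels <- factor(sample(c("neg", "pos"), n, replace = TRUE,
                            prob = c(0.5, 0.5)), levels = c("neg", "pos"))
    if (length(unique(labels)) < 2) next
    # coarse scores force ties so the one-half convention is exercised
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(auc_rank(scores, labels), concordance_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc_rank(1:4, rep("a", 4)), "2 classes")
})

test_that("sparse classifier is deterministic, separable-exact and leak-free", {
  # perfectly separable two-feature data
  set.seed(1)
  n <- 40
  x <- cbind(c(stats::rnorm(n / 2, 0, 0.1), stats::rnorm(n / 2, 5, 0.1)),
             stats::rnorm(n))
  x <- x - min(x)
  y <- rep(c("ctrl", "case"), each = n / 2)
  fit <- fit_sparse_classifier(x, y, cv_folds = 4, n_boot = 100, seed = 2)
  set.seed(99)
  xv <- cbind(c(stats::rnorm(10, 0, 0.1), stats::rnorm(10, 5, 0.1)),
              stats::rnorm(20))
  xv <- xv - min(x)
  yv <- rep(c("ctrl", "case"), each = 10)
  expect_equal(auc_rank(predict(fit, xv), yv), 1)
  expect_equal(fit$auc, 1)
  # determinism under the seed
  fit2 <- fit_sparse_classifier(x, y, cv_folds = 4, n_boot = 100, seed = 2)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$lambda, fit2$lambda)
  # information hygiene: the fitted model never sees validation rows, so
  # coefficients are identical whatever data is later scored
  p1 <- predict(fit, xv)
  p2 <- predict(fit, xv * 2)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_false(identical(p1, p2))
  # degenerate folds are refused with guidance
  expect_error(fit_sparse_classifier(x[c(1:3, 21:40), ], y[c(1:3, 21:40)],
                                     cv_folds = 5), "reduce cv_folds")
})

test_that("single planted marker reaches the binormal AUC and null stays at chance", {
  fm <- make_binormal_matrix(n_per_group = 200, n_features = 10, d = 2,
                             seed = 31)
  fit <- fit_sparse_classifier(fm, fm$labels, nlambda = 30, n_boot = 100,
                               seed = 32)
  expect_lt(abs(fit$cv_auc - stats::pnorm(2 / sqrt(2))), 0.05)
  # null cohorts: median tuned CV-AUC within [0.4, 0.6]
  aucs <- vapply(1:20, function(s) {
    fm0 <- make_null_matrix(n_per_group = 30, n_features = 20, seed = 100 + s)
    fit_sparse_classifier(fm0, fm0$labels, cv_folds = 5, nlambda = 20,
                          n_boot = 50, seed = s)$cv_auc
  }, numeric(1))
  expect_gte(stats::median(aucs), 0.4)
  expect_lte(stats::median(aucs), 0.6)
})

test_that("ROC identities, bootstrap CI and curve endpoints are correct", {
  y <- rep(c("neg", "pos"), each = 20)
  p <- as.numeric(y == "pos")
  r <- roc_with_ci(p, y, n_boot = 200, seed = 1)
  expect_equal(r$auc, 1)
  r2 <- roc_with_ci(1 - p, y, n_boot = 200, seed = 1)
  expect_equal(r2$auc, 0)
  # CI contains the point AUC on noisy scores
  set.seed(2)
  s <- stats::rnorm(40) + as.numeric(y == "pos")
  r3 <- roc_with_ci(s, y, n_boot = 500, seed = 3)
  expect_gte(r3$auc, r3$ci[1])
  expect_lte(r3$auc, r3$ci[2])
  # curve runs from (0,0) to (1,1)
  expect_equal(unlist(r3$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r3$curve[nrow(r3$curve), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_error(roc_with_ci(p[1:20], y[1:20], n_boot = 10), "2 classes")
})

test_that("operating point matches the exhaustive threshold scan", {
  # separable case: perfect operating point
  y <- rep(c("neg", "pos"), each = 10)
  op <- operating_point(as.numeric(y == "pos"), y)
  expect_equal(c(op$sensitivity, op$specificity, op$accuracy), c(1, 1, 1))
  # all probabilities equal: all-positive convention
  op2 <- operating_point(rep(0.4, 20), y)
  expect_equal(op2$sensitivity, 1)
  expect_equal(op2$specificity, 0)
  # brute-force scan oracle on random inputs
  for (rep in 1:10) {
    set.seed(rep)
    n <- sample(20:100, 1)
    yy <- factor(sample(c("a", "b"), n, replace = TRUE), levels = c("a", "b"))
    if (length(unique(yy)) < 2) next
    pp <- round(stats::runif(n), 2)
    op3 <- operating_point(pp, yy)
    best_j <- max(vapply(unique(pp), function(t) {
      pred <- pp >= t
      sum(pred & yy == "b") / sum(yy == "b") +
        sum(!pred & yy == "a") / sum(yy == "a") - 1
    }, numeric(1)))
    expect_equal(op3$sensitivity + op3$specificity - 1, best_j,
                 tolerance = 1e-12)
  }
  # fixed rule applies the supplied cut
  op4 <- operating_point(c(0.2, 0.8, 0.3, 0.9), c("neg", "pos", "neg", "pos"),
                         rule = "fixed", threshold = 0.5)
  expect_equal(op4$threshold, 0.5)
  expect_equal(op4$accuracy, 1)
})

test_that("permutation test attains the add-one floor under strong signal", {
  fm <- make_binormal_matrix(n_per_group = 50, n_features = 10, d = 2,
                             seed = 41)
  pt <- permutation_test(fm, fm$labels, n_perm = 199, cv_folds = 3,
                         nlambda = 10, seed = 42)
  expect_equal(pt$p_value, 1 / 200)
  expect_gte(pt$p_value, 1 / (199 + 1))
  expect_length(pt$null_auc, 199)
})

test_that("PCA agrees with the covariance eigen-decomposition", {
  # rank-1 matrix: first component explains > 99.9% of variance
  set.seed(5)
  u <- stats::rnorm(12); v <- abs(stats::rnorm(6))
  r1 <- outer(u, v) + matrix(stats::rnorm(72, 0, 1e-5), 12, 6)
  pc <- pca_scores(r1, n_components = 2)
  expect_gt(pc$explained_variance[1], 0.999)
  # scores are orthogonal
  g <- crossprod(pc$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # eigen-decomposition oracle on a 5 x 4 matrix
  set.seed(6)
  m <- matrix(stats::rnorm(20), 5, 4)
  pc2 <- pca_scores(m, n_components = 3)
  Z <- scale(m)
  ev <- eigen(stats::cov(Z))
  expect_equal(pc2$explained_variance,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-10)
  for (j in 1:3) {
    expect_equal(abs(pc2$scores[, j]), abs(Z %*% ev$vectors[, j])[, 1],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # constant features are dropped with a warning
  m2 <- cbind(m, 7)
  expect_warning(pca_scores(m2, 2), "constant")
  # explained variance is non-increasing
  expect_true(all(diff(pc2$explained_variance) <= 1e-12))
})
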
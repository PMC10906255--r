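# Sparse (L1-penalized logistic) diagnosis: cohort splitting, tuned
# cross-validated AUC, ROC with bootstrap CI, operating point, permutation
# test, unsupervised PCA. The penalized solver is glmnet; fold handling,
# lambda choice and the rank-statistic AUC live here so the permutation
# test can rerun the identical tuning procedure.

.fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

# Two-class labels. A factor keeps its level order (second level = case);
# character labels are ordered by first appearance, so the control group
# listed first in a cohort spec stays the reference class.
.binary_y <- function(y) {
  f <- if (is.factor(y)) droplevels(y) else factor(y, levels = unique(y))
  if (nlevels(f) != 2) stop("exactly 2 classes are required, got ", nlevels(f))
  f
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from ranks (equivalent to the
#' pairwise concordance fraction with ties counted one half); the positive
#' class is the second factor level.
#'
#' @param scores Numeric scores or probabilities.
#' @param labels Two-class labels; second factor level = positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  f <- .binary_y(labels)
  pos <- f == levels(f)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.stratified_folds <- function(f, k) {
  foldid <- integer(length(f))
  for (lev in levels(f)) {
    idx <- which(f == lev)
    if (length(idx) < k) {
      stop("class '", lev, "' has fewer members (", length(idx),
           ") than cv_folds = ", k, "; reduce cv_folds")
    }
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

.lambda_grid <- function(X, y01, nlambda = 50, ratio = 1e-3) {
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, y01 - mean(y01)))) / n
  lmax <- max(lmax, 1e-6)
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

# mean held-out AUC per lambda over stratified folds; returns the grid,
# the per-lambda mean AUC and the chosen (AUC-maximizing, sparsest) lambda
.tune_cv_auc <- function(Xs, f, lambda, cv_folds) {
  foldid <- .stratified_folds(f, cv_folds)
  y01 <- as.integer(f) - 1L
  aucs <- matrix(NA_real_, cv_folds, length(lambda))
  for (k in seq_len(cv_folds)) {
    tr <- foldid != k
    fit <- glmnet::glmnet(Xs[tr, , drop = FALSE], f[tr], family = "binomial",
                          lambda = lambda, standardize = FALSE)
    lp <- predict(fit, Xs[!tr, , drop = FALSE], s = lambda)
    aucs[k, ] <- apply(lp, 2, auc_rank, labels = f[!tr])
  }
  mean_auc <- colMeans(aucs)
  best <- which.max(mean_auc) # grid is descending: ties pick sparsest
  list(lambda = lambda, mean_auc = mean_auc, best = best,
       cv_auc = mean_auc[best], foldid = foldid)
}

#' Stratified discovery/validation split with covariate balance report
#'
#' @param metadata data.frame with columns `sample_id`, `group` and
#'   optionally `age` and `sex`.
#' @param validation_fraction Fraction of each group held out (in (0, 1)).
#' @param seed Integer seed.
#' @return List with `discovery_ids`, `validation_ids`, `balance` (the
#'   [covariate_balance()] report for the discovery cohort) and `seed`.
#' @export
split_cohort <- function(metadata, validation_fraction = 0.3, seed = 1) {
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)")
  }
  stopifnot(all(c("sample_id", "group") %in% names(metadata)))
  if (any(table(metadata$group) < 2)) stop("every group needs >= 2 members")
  set.seed(seed)
  val <- unlist(lapply(split(metadata$sample_id, metadata$group), function(ids) {
    sample(ids, max(1, round(length(ids) * validation_fraction)))
  }), use.names = FALSE)
  disc <- setdiff(metadata$sample_id, val)
  bal <- covariate_balance(metadata[metadata$sample_id %in% disc, ])
  list(discovery_ids = disc, validation_ids = val, balance = bal, seed = seed)
}

#' Covariate balance tests between groups
#'
#' Age is compared by a rank-sum (Wilcoxon / Kruskal-Wallis) test, sex by
#' a chi-square test, mirroring the demographic checks reported alongside
#' cohort splits.
#'
#' @param metadata data.frame with `group` and optionally `age`, `sex`.
#' @return data.frame with columns `variable`, `test`, `p`.
#' @export
covariate_balance <- function(metadata) {
  out <- list()
  g <- factor(metadata$group)
  if ("age" %in% names(metadata)) {
    p <- if (nlevels(g) == 2) {
      stats::wilcox.test(metadata$age ~ g, exact = FALSE)$p.value
    } else stats::kruskal.test(metadata$age, g)$p.value
    out[[length(out) + 1]] <- data.frame(variable = "age", test = "rank-sum",
                                         p = p)
  }
  if ("sex" %in% names(metadata)) {
    p <- suppressWarnings(
      stats::chisq.test(table(metadata$sex, g))$p.value)
    out[[length(out) + 1]] <- data.frame(variable = "sex", test = "chi-square",
                                         p = p)
  }
  if (!length(out)) return(data.frame(variable = character(),
                                      test = character(), p = numeric()))
  do.call(rbind, out)
}

#' Fit the sparse diagnostic classifier
#'
#' L1-penalized logistic regression. Features are standardized with
#' discovery statistics only; the penalty is chosen by maximizing the mean
#' cross-validated rank-AUC over stratified folds, then the model is refit
#' on the full discovery set at that penalty. Discovery AUC (with
#' stratified-bootstrap CI) and the Youden operating point are attached.
#'
#' @param x Discovery [feature_matrix()] or numeric matrix (samples x
#'   features).
#' @param y Two-class labels; the second factor level is the case class.
#' @param lambda_grid Optional penalty grid (descending); default 50
#'   log-spaced values from the data-derived maximum.
#' @param cv_folds Number of stratified CV folds.
#' @param nlambda Grid length when `lambda_grid` is NULL.
#' @param n_boot Bootstrap resamples for the discovery AUC CI.
#' @param seed Integer seed (folds and bootstrap).
#' @return An object of class `sparse_model`; see Details.
#' @details The result carries `coefficients` (named, standardized scale),
#'   `intercept`, `lambda`, `cv_auc` (mean held-out AUC at the chosen
#'   penalty — the tuning statistic), `auc`/`auc_ci` (refit discovery AUC),
#'   `sensitivity`/`specificity`/`accuracy`/`threshold` (Youden point on
#'   discovery), `probabilities`, standardization constants and the seed.
#'   Use [predict()] with new data to obtain validation probabilities; the
#'   stored discovery standardization is applied.
#' @export
fit_sparse_classifier <- function(x, y, lambda_grid = NULL, cv_folds = 5,
                                  nlambda = 50, n_boot = 1000, seed = 1) {
  X <- .fm_values(x)
  f <- .binary_y(y)
  stopifnot(nrow(X) == length(f))
  set.seed(seed)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  y01 <- as.integer(f) - 1L
  if (is.null(lambda_grid)) lambda_grid <- .lambda_grid(Xs, y01, nlambda)
  tune <- .tune_cv_auc(Xs, f, lambda_grid, cv_folds)
  fit <- glmnet::glmnet(Xs, f, family = "binomial", lambda = lambda_grid,
                        standardize = FALSE)
  beta <- as.numeric(predict(fit, s = tune$lambda[tune$best],
                             type = "coefficients"))
  names(beta) <- c("(Intercept)", colnames(X))
  prob <- as.numeric(stats::plogis(beta[1] + Xs %*% beta[-1]))
  roc <- roc_with_ci(prob, f, n_boot = n_boot, seed = seed + 1L)
  op <- operating_point(prob, f, rule = "youden")
  structure(list(
    coefficients = beta[-1], intercept = beta[[1]],
    lambda = tune$lambda[tune$best], lambda_grid = lambda_grid,
    cv_auc = tune$cv_auc, cv_auc_path = tune$mean_auc,
    auc = roc$auc, auc_ci = roc$ci,
    sensitivity = op$sensitivity, specificity = op$specificity,
    accuracy = op$accuracy, threshold = op$threshold,
    probabilities = prob, center = center, scale = scale,
    levels = levels(f), cv_folds = cv_folds, seed = seed
  ), class = "sparse_model")
}

#' @export
print.sparse_model <- function(x, ...) {
  cat("sparse_model:", sum(x$coefficients != 0), "of",
      length(x$coefficients), "features selected (lambda =",
      signif(x$lambda, 3), ")\n")
  cat(sprintf("  CV AUC %.3f | discovery AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$cv_auc, x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  Youden: sens %.3f spec %.3f acc %.3f @ %.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$threshold))
  invisible(x)
}

#' Predict case probabilities from a fitted sparse model
#'
#' @param object A `sparse_model`.
#' @param newdata A [feature_matrix()] or numeric matrix with the same
#'   features (columns) as the discovery matrix.
#' @param ... Unused.
#' @return Numeric vector of class-1 (case) probabilities.
#' @export
predict.sparse_model <- function(object, newdata, ...) {
  X <- .fm_values(newdata)
  stopifnot(ncol(X) == length(object$coefficients))
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  as.numeric(stats::plogis(object$intercept + Xs %*% object$coefficients))
}

#' ROC curve and AUC with stratified bootstrap CI
#'
#' AUC by the rank statistic ([auc_rank()]); the confidence interval is a
#' stratified bootstrap percentile interval (cases and controls resampled
#' separately).
#'
#' @param probabilities Numeric scores.
#' @param labels Two-class labels; second level = positive.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return List with `auc`, `ci` (length-2), `curve` (data.frame
#'   `threshold`, `fpr`, `tpr`) and `n_boot`.
#' @export
roc_with_ci <- function(probabilities, labels, n_boot = 2000, conf = 0.95,
                        seed = 1) {
  f <- .binary_y(labels)
  auc <- auc_rank(probabilities, f)
  pos <- which(f == levels(f)[2]); neg <- which(f == levels(f)[1])
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auc_rank(probabilities[i], f[i])
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(a, 1 - a)))
  th <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  curve <- do.call(rbind, lapply(th, function(t) {
    pred <- probabilities >= t
    data.frame(threshold = t,
               fpr = sum(pred & f == levels(f)[1]) / length(neg),
               tpr = sum(pred & f == levels(f)[2]) / length(pos))
  }))
  list(auc = auc, ci = ci, curve = curve, n_boot = n_boot)
}

#' Classification operating point
#'
#' Youden rule: the threshold maximizing J = sensitivity + specificity - 1
#' over observed probabilities (samples with probability >= threshold are
#' called positive; at a tie the smallest threshold, i.e. the
#' all-positive-leaning cut, is used). The fixed rule applies a given
#' probability cut, e.g. 0.5.
#'
#' @param probabilities Numeric scores.
#' @param labels Two-class labels; second level = positive.
#' @param rule `"youden"` or `"fixed"`.
#' @param threshold Probability cut for `rule = "fixed"`.
#' @return List with `sensitivity`, `specificity`, `accuracy`, `threshold`.
#' @export
operating_point <- function(probabilities, labels,
                            rule = c("youden", "fixed"), threshold = 0.5) {
  rule <- match.arg(rule)
  f <- .binary_y(labels)
  pos <- f == levels(f)[2]
  eval_at <- function(t) {
    pred <- probabilities >= t
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    c(sens = sens, spec = spec, acc = mean(pred == pos))
  }
  if (rule == "fixed") {
    m <- eval_at(threshold)
  } else {
    cand <- sort(unique(probabilities))
    stats_m <- vapply(cand, eval_at, numeric(3))
    J <- stats_m["sens", ] + stats_m["spec", ] - 1
    best <- which(J == max(J))[1] # tie: smallest threshold (all-positive)
    threshold <- cand[best]
    m <- stats_m[, best]
  }
  list(sensitivity = unname(m["sens"]), specificity = unname(m["spec"]),
       accuracy = unname(m["acc"]), threshold = threshold)
}

#' Permutation test of the tuned cross-validated AUC
#'
#' The class labels are permuted `n_perm` times and the complete tuning
#' procedure (standardization, lambda grid, stratified CV, penalty choice)
#' is rerun on each permutation; the statistic is the tuned mean CV AUC,
#' identical to the observed pipeline, so the null is exchangeable. The
#' p-value uses the add-one rule, p = (1 + #\{perm >= observed\}) /
#' (1 + n_perm).
#'
#' @param x [feature_matrix()] or numeric matrix.
#' @param y Two-class labels.
#' @param n_perm Number of permutations (>= 100 recommended; smaller
#'   values are allowed for calibration studies).
#' @param cv_folds Stratified CV folds for each fit.
#' @param nlambda Penalty-grid length.
#' @param seed Integer seed.
#' @return List with `p_value`, `observed_auc` and `null_auc` (vector).
#' @export
permutation_test <- function(x, y, n_perm = 1000, cv_folds = 5,
                             nlambda = 30, seed = 1) {
  X <- .fm_values(x)
  f <- .binary_y(y)
  set.seed(seed)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd); scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  stat <- function(fy) {
    lam <- .lambda_grid(Xs, as.integer(fy) - 1L, nlambda)
    .tune_cv_auc(Xs, fy, lam, cv_folds)$cv_auc
  }
  observed <- stat(f)
  null_auc <- vapply(seq_len(n_perm), function(b) stat(sample(f)), numeric(1))
  list(p_value = (1 + sum(null_auc >= observed)) / (1 + n_perm),
       observed_auc = observed, null_auc = null_auc)
}

#' Unsupervised PCA scores of a feature matrix
#'
#' Principal components of the mean-centred, unit-variance-scaled matrix.
#' Constant features are dropped with a warning before scaling.
#'
#' @param x [feature_matrix()] or numeric matrix.
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components), `explained_variance`
#'   (fractions, non-increasing) and `loadings`.
#' @export
pca_scores <- function(x, n_components = 2) {
  X <- .fm_values(x)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped before scaling")
    X <- X[, sds > 0, drop = FALSE]
  }
  stopifnot(n_components <= min(dim(X)))
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)],
       loadings = pr$rotation[, seq_len(n_components), drop = FALSE])
}
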
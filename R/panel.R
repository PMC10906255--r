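# Four-criterion biomarker screen (selection frequency, rank-sum p,
# abundance, single-feature AUC), fold-change statistics, panel model and
# heatmap summary.

#' Screening criteria for the biomarker panel
#'
#' @param min_frequency Minimum bootstrap selection frequency (default 0.90).
#' @param max_p Maximum raw rank-sum p (default 0.05).
#' @param min_abundance Minimum mean normalized intensity (default 500,
#'   same arbitrary units as the intensities).
#' @param min_auc Minimum single-feature AUC (default 0.7).
#' @param n_resamples Number of resample fits for the frequency (>= 50).
#' @return An object of class `screening_criteria`.
#' @export
screening_criteria <- function(min_frequency = 0.90, max_p = 0.05,
                               min_abundance = 500, min_auc = 0.7,
                               n_resamples = 100) {
  stopifnot(min_frequency >= 0, min_frequency <= 1,
            max_p > 0, max_p <= 1, min_abundance >= 0,
            min_auc >= 0, min_auc <= 1, n_resamples >= 50)
  structure(list(min_frequency = min_frequency, max_p = max_p,
                 min_abundance = min_abundance, min_auc = min_auc,
                 n_resamples = as.integer(n_resamples)),
            class = "screening_criteria")
}

#' Selection frequency of each feature under resampling
#'
#' Stratified subsamples (`fraction`, default 80%, of the discovery
#' samples, drawn without replacement) are refit with the L1-penalized
#' classifier at a fixed tuned penalty; the frequency is the fraction of
#' fits in which a feature's coefficient is nonzero (stability-selection
#' style).
#'
#' @param x Discovery [feature_matrix()] or numeric matrix.
#' @param y Two-class labels.
#' @param lambda Penalty; if NULL it is tuned once with
#'   [fit_sparse_classifier()] on the full discovery set.
#' @param n_resamples Number of resample fits.
#' @param fraction Subsample fraction per resample.
#' @param cv_folds Folds used if `lambda` must be tuned.
#' @param seed Integer seed.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
feature_frequency <- function(x, y, lambda = NULL, n_resamples = 100,
                              fraction = 0.8, cv_folds = 5, seed = 1) {
  X <- .fm_values(x)
  f <- .binary_y(y)
  if (is.null(lambda)) {
    lambda <- fit_sparse_classifier(X, f, cv_folds = cv_folds, n_boot = 100,
                                    seed = seed)$lambda
  }
  set.seed(seed)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd); scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  # glmnet needs a short descending path ending at the target lambda
  path <- c(lambda * 4, lambda * 2, lambda)
  count <- numeric(ncol(X))
  for (b in seq_len(n_resamples)) {
    idx <- unlist(lapply(levels(f), function(lev) {
      i <- which(f == lev)
      sample(i, max(2, floor(length(i) * fraction)))
    }), use.names = FALSE)
    fit <- glmnet::glmnet(Xs[idx, , drop = FALSE], f[idx],
                          family = "binomial", lambda = path,
                          standardize = FALSE)
    beta <- as.numeric(predict(fit, s = lambda, type = "coefficients"))[-1]
    count <- count + (beta != 0)
  }
  stats::setNames(count / n_resamples, colnames(X))
}

#' Per-feature differential statistics
#'
#' Two-sided Wilcoxon rank-sum p (BH-adjusted q alongside), mean
#' abundance over all samples, single-feature AUC oriented to be >= 0.5
#' (the natural direction is recorded separately), and case/control fold
#' change. Constant features get p = 1 and AUC = 0.5 by convention; a
#' fold change of exactly 1 is labelled "up" (documented tie convention).
#'
#' @param x [feature_matrix()] or numeric matrix of normalized intensities.
#' @param y Two-class labels; second factor level = case.
#' @return data.frame with one row per feature: `feature`, `mz` (NA when
#'   unavailable), `p`, `q`, `abundance`, `auc_single`, `fold_change`,
#'   `direction`.
#' @export
feature_stats <- function(x, y) {
  X <- .fm_values(x)
  f <- .binary_y(y)
  if (any(table(f) < 3)) stop("both classes need >= 3 samples")
  case <- f == levels(f)[2]
  mz <- if (inherits(x, "feature_matrix")) x$feature_mz
    else rep(NA_real_, ncol(X))
  p <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (stats::sd(v) == 0) return(1)
    # exact p for small tie-free samples, normal approximation otherwise
    suppressWarnings(stats::wilcox.test(v[case], v[!case])$p.value)
  }, numeric(1))
  auc_dir <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(X[, j]) == 0) return(0.5)
    auc_rank(X[, j], f)
  }, numeric(1))
  m_case <- colMeans(X[case, , drop = FALSE])
  m_ctrl <- colMeans(X[!case, , drop = FALSE])
  fc <- ifelse(m_ctrl > 0, m_case / m_ctrl, NA_real_)
  out <- data.frame(
    feature = colnames(X) %||% sprintf("F%d", seq_len(ncol(X))),
    mz = mz,
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    abundance = colMeans(X),
    auc_single = pmax(auc_dir, 1 - auc_dir),
    fold_change = fc,
    direction = ifelse(!is.na(fc) & fc < 1, "down", "up"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the four screening criteria
#'
#' Intersects the four criterion sets (frequency, p value, abundance,
#' single-feature AUC); deterministic given the statistics. An empty panel
#' is returned with a warning, not an error.
#'
#' @param stats [feature_stats()] table.
#' @param frequency Named frequency vector from [feature_frequency()],
#'   aligned with `stats$feature`.
#' @param criteria A [screening_criteria()].
#' @return List of class `panel_report` with `panel` (surviving rows of
#'   `stats` plus `frequency`), `criteria` and per-criterion pass counts.
#' @export
screen_panel <- function(stats, frequency, criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"),
            length(frequency) == nrow(stats))
  # closed boundaries so vacuous criteria (max_p = 1, min_auc = 0.5, ...)
  # admit every feature; at the default working points the distinction
  # from the strict reading is measure-zero
  pass <- cbind(
    frequency = frequency >= criteria$min_frequency,
    p = stats$p <= criteria$max_p,
    abundance = stats$abundance > criteria$min_abundance,
    auc = stats$auc_single >= criteria$min_auc
  )
  keep <- rowSums(pass) == 4L
  panel <- cbind(stats[keep, , drop = FALSE],
                 frequency = unname(frequency[keep]))
  rownames(panel) <- NULL
  if (!nrow(panel)) warning("no feature passes all four screening criteria")
  structure(list(panel = panel, criteria = criteria,
                 n_pass = colSums(pass)), class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat("panel_report:", nrow(x$panel), "features pass all four criteria\n")
  cat("  per-criterion pass counts:",
      paste(names(x$n_pass), x$n_pass, sep = "=", collapse = ", "), "\n")
  if (nrow(x$panel)) {
    print(x$panel[, c("feature", "p", "abundance", "auc_single",
                      "fold_change", "direction", "frequency")])
  }
  invisible(x)
}

#' Unpenalized logistic model on the screened panel
#'
#' Ordinary logistic regression on the panel features; if the fit is
#' separable (non-converged or fitted probabilities at 0/1) the model is
#' refit with a small ridge penalty. AUC and CI come from [roc_with_ci()].
#'
#' @param x Discovery [feature_matrix()] or matrix restricted to (or
#'   indexed by) the panel.
#' @param y Two-class labels.
#' @param features Optional column names/indices selecting the panel.
#' @param n_boot Bootstrap resamples for the AUC CI.
#' @param seed Integer seed.
#' @return List of class `panel_model` with `coefficients`, `probabilities`,
#'   `auc`, `auc_ci`, `operating_point`, `ridged` flag.
#' @export
panel_model <- function(x, y, features = NULL, n_boot = 1000, seed = 1) {
  X <- .fm_values(x)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  if (!ncol(X)) stop("empty panel")
  f <- .binary_y(y)
  df <- data.frame(X, check.names = TRUE)
  fit <- suppressWarnings(
    stats::glm(f ~ ., family = stats::binomial(), data = df))
  pr <- as.numeric(stats::fitted(fit))
  ridged <- !fit$converged || any(pr < 1e-8 | pr > 1 - 1e-8)
  coefs <- stats::coef(fit)
  if (ridged) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd); scale[scale == 0] <- 1
    Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
    # small ridge jitter stabilizes separable panels
    rfit <- glmnet::glmnet(Xs, f, family = "binomial", alpha = 0,
                           lambda = c(1, 0.1, 0.01), standardize = FALSE)
    beta <- as.numeric(predict(rfit, s = 0.01, type = "coefficients"))
    pr <- as.numeric(stats::plogis(beta[1] + Xs %*% beta[-1]))
    b_orig <- beta[-1] / scale
    coefs <- stats::setNames(c(beta[1] - sum(b_orig * center), b_orig),
                             c("(Intercept)", colnames(X)))
  }
  roc <- roc_with_ci(pr, f, n_boot = n_boot, seed = seed)
  structure(list(coefficients = coefs, probabilities = pr,
                 auc = roc$auc, auc_ci = roc$ci,
                 operating_point = operating_point(pr, f), ridged = ridged),
            class = "panel_model")
}

#' Row-standardized heatmap matrix of the panel
#'
#' Each panel feature is standardized to mean 0, sd 1 across samples
#' (constant features dropped with a warning); samples are ordered by
#' group and, within group, by the panel-model case probability.
#'
#' @param x [feature_matrix()] or matrix restricted to the panel features.
#' @param y Group labels (any number of groups).
#' @param probabilities Optional per-sample ordering score (e.g. the
#'   [panel_model()] probabilities); defaults to the first feature.
#' @return List with `matrix` (features x samples, standardized) and
#'   `sample_order` (indices into the input rows).
#' @export
heatmap_matrix <- function(x, y, probabilities = NULL) {
  X <- .fm_values(x)
  if (!ncol(X)) stop("empty panel")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant panel feature(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X) # samples x features, feature-wise standardization
  if (is.null(probabilities)) probabilities <- X[, 1]
  ord <- order(factor(y), probabilities)
  list(matrix = t(Z[ord, , drop = FALSE]), sample_order = ord)
}
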
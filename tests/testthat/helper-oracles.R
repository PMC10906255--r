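# Independent oracles used to cross-check the package implementations.
# These are deliberately brute-force and share no code with the package.

# AUC as the O(n^2) pairwise concordance fraction (ties count one half);
# positive class = second level in order of first appearance.
concordance_auc <- function(scores, labels) {
  f <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  s1 <- scores[f == levels(f)[2]]
  s0 <- scores[f == levels(f)[1]]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# Exhaustive two-sided rank-sum p for small samples (no ties): enumerate
# every assignment of the pooled values to the case group and compare the
# doubled smaller tail of the rank-sum statistic, the same two-sided
# convention as the exact Wilcoxon test.
enum_ranksum_p <- function(x_case, x_ctrl) {
  pooled <- c(x_case, x_ctrl)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x_case)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  stat <- apply(sets, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(stat <= obs), mean(stat >= obs)))
}

# Hypergeometric upper-tail P(X >= ov) by direct combinatorial summation.
enum_hyper_p <- function(N, K, k, ov) {
  j <- ov:min(K, k)
  sum(choose(K, j) * choose(N - K, k - j)) / choose(N, k)
}

# Canonical form of a cluster assignment (relabelled by first appearance)
# so two partitions can be compared for equality.
partition_canon <- function(cl) {
  match(cl, unique(cl))
}

# Exhaustive single-linkage clustering of 1-D positions cut at height tol,
# via the generic hierarchical-clustering machinery.
single_linkage_oracle <- function(mz, tol) {
  if (length(mz) == 1) return(1L)
  hc <- stats::hclust(stats::dist(mz), method = "single")
  stats::cutree(hc, h = tol)
}

# Small two-group log-normal feature matrix with one planted standardized
# effect in column 1 (binormal single-marker cohort).
make_binormal_matrix <- function(n_per_group, n_features, d, sdlog = 0.3,
                                 seed = 1) {
  set.seed(seed)
  labels <- rep(c("control", "case"), each = n_per_group)
  mu <- matrix(7, 2 * n_per_group, n_features)
  mu[labels == "case", 1] <- 7 + d * sdlog
  vals <- exp(matrix(stats::rnorm(length(mu), mu, sdlog), nrow(mu)))
  feature_matrix(vals, feature_mz = 100 + seq_len(n_features),
                 sample_ids = sprintf("S%03d", seq_len(nrow(mu))),
                 labels = labels)
}

# Pure-noise (label-independent) feature matrix.
make_null_matrix <- function(n_per_group, n_features, seed = 1) {
  make_binormal_matrix(n_per_group, n_features, d = 0, seed = seed)
}
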
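# Four-criterion biomarker screen, panel model and heatmap summary.

test_that("selection frequency separates dominating from noise features", {
  fm <- make_binormal_matrix(n_per_group = 60, n_features = 15, d = 3,
                             seed = 11)
  fr <- feature_frequency(fm, fm$labels, n_resamples = 100, seed = 12)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(unname(fr[1]), 1.0) # the planted dominating feature
  expect_lt(stats::median(fr[-1]), 0.5)
  # reproducible under a fixed seed
  fr2 <- feature_frequency(fm, fm$labels, n_resamples = 100, seed = 12)
  expect_identical(fr, fr2)
})

test_that("feature statistics: conventions, power and enumeration oracle", {
  # constant feature: p = 1, AUC = 0.5, fold change 1, direction 'up'
  vals <- cbind(rep(5, 12), c(stats::rnorm(6, 10), stats::rnorm(6, 14)))
  vals <- pmax(vals, 0)
  st <- feature_stats(vals, rep(c("ctrl", "case"), each = 6))
  expect_equal(st$p[1], 1)
  expect_equal(st$auc_single[1], 0.5)
  expect_equal(st$fold_change[1], 1)
  expect_equal(st$direction[1], "up")
  # rank-sum p agrees with the exhaustive 4v4 permutation distribution
  for (rep in 1:5) {
    set.seed(rep)
    a <- stats::runif(4, 1, 2)
    b <- stats::runif(4, 1.2, 2.4)
    st2 <- feature_stats(cbind(c(a, b)), rep(c("ctrl", "case"), each = 4))
    expect_equal(st2$p, enum_ranksum_p(b, a), tolerance = 1e-12)
  }
  # planted up-regulated feature at d = 2, n = 100/group: q < 0.05 and
  # single AUC > 0.9 in at least 9 of 10 seeds
  hits <- vapply(1:10, function(s) {
    fm <- make_binormal_matrix(n_per_group = 100, n_features = 20, d = 2,
                               seed = 200 + s)
    st3 <- feature_stats(fm, fm$labels)
    st3$q[1] < 0.05 && st3$auc_single[1] > 0.9 && st3$direction[1] == "up"
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("screening is vacuous-complete, monotone and deterministic", {
  fm <- make_binormal_matrix(n_per_group = 40, n_features = 12, d = 2,
                             seed = 21)
  st <- feature_stats(fm, fm$labels)
  fr <- feature_frequency(fm, fm$labels, n_resamples = 50, seed = 22)
  # vacuous criteria admit every feature
  vac <- screening_criteria(min_frequency = 0, max_p = 1, min_abundance = 0,
                            min_auc = 0, n_resamples = 50)
  expect_equal(nrow(screen_panel(st, fr, vac)$panel), 12)
  # raising any single threshold never enlarges the panel
  base_n <- nrow(screen_panel(st, fr, screening_criteria(n_resamples = 50))$panel)
  for (tweak in list(list(min_frequency = 0.95), list(max_p = 0.01),
                     list(min_abundance = 800), list(min_auc = 0.8))) {
    args <- utils::modifyList(list(n_resamples = 50), tweak)
    crit <- do.call(screening_criteria, args)
    expect_lte(nrow(suppressWarnings(screen_panel(st, fr, crit))$panel), base_n)
  }
  # deterministic given stats
  expect_identical(screen_panel(st, fr)$panel, screen_panel(st, fr)$panel)
  # empty panel warns rather than errors
  strict <- screening_criteria(min_frequency = 1, max_p = 1e-12,
                               min_abundance = 1e9, min_auc = 0.999,
                               n_resamples = 50)
  expect_warning(pr <- screen_panel(st, fr, strict), "no feature")
  expect_equal(nrow(pr$panel), 0)
})

test_that("panel model: single-feature consistency, gain, and null behaviour", {
  # single-feature panel AUC equals that feature's (oriented) single AUC
  fm <- make_binormal_matrix(n_per_group = 50, n_features = 5, d = 1.5,
                             seed = 31)
  pm <- panel_model(fm, fm$labels, features = 1, n_boot = 100, seed = 32)
  st <- feature_stats(fm, fm$labels)
  expect_equal(pm$auc, st$auc_single[1], tolerance = 1e-6)
  # eight independent markers at d = 1: combination beats the best single
  gain <- vapply(1:20, function(s) {
    set.seed(300 + s)
    n <- 60
    labels <- rep(c("ctrl", "case"), each = n)
    mu <- outer(as.numeric(labels == "case"), rep(0.3, 8)) + 7
    vals <- exp(matrix(stats::rnorm(2 * n * 8, mu, 0.3), 2 * n, 8))
    fm8 <- feature_matrix(vals, 100 + 1:8, sprintf("S%d", 1:(2 * n)),
                          labels = labels)
    pm8 <- panel_model(fm8, fm8$labels, n_boot = 50, seed = s)
    st8 <- feature_stats(fm8, fm8$labels)
    pm8$auc > max(st8$auc_single)
  }, logical(1))
  expect_gte(mean(gain), 0.85)
  # label-independent data: out-of-sample panel AUC is chance
  # (median over 20 seeds within [0.45, 0.55])
  null_auc <- vapply(1:20, function(s) {
    fm0 <- make_null_matrix(n_per_group = 40, n_features = 6, seed = 400 + s)
    fme <- make_null_matrix(n_per_group = 40, n_features = 6, seed = 900 + s)
    pm0 <- panel_model(fm0, fm0$labels, n_boot = 50, seed = s)
    lp <- pm0$coefficients[1] +
      fme$values %*% pm0$coefficients[-1]
    auc_rank(as.numeric(lp), fme$labels)
  }, numeric(1))
  expect_gte(stats::median(null_auc), 0.45)
  expect_lte(stats::median(null_auc), 0.55)
  expect_error(panel_model(fm, fm$labels, features = integer(0)), "empty")
})

test_that("separable panels are stabilized with a ridge fallback", {
  set.seed(41)
  labels <- rep(c("ctrl", "case"), each = 15)
  v <- c(stats::rnorm(15, 2, 0.1), stats::rnorm(15, 10, 0.1)) # separable
  fm <- feature_matrix(cbind(v, abs(stats::rnorm(30)) + 1), c(150, 250),
                       sprintf("S%d", 1:30), labels = labels)
  pm <- suppressWarnings(panel_model(fm, fm$labels, n_boot = 50, seed = 42))
  expect_true(pm$ridged)
  expect_equal(pm$auc, 1)
  expect_true(all(is.finite(pm$coefficients)))
})

test_that("heatmap matrix is standardized, scale-invariant and direction-true", {
  lib <- build_template_library(n_background = 10, n_differential = 4,
                                effect_size = 2, seed = 51)
  fm <- simulate_feature_matrix(cohort_spec(c(SCOPD = 25, AECOPD = 25),
                                            seed = 52),
                                lib$templates, noise_spec(dropout_prob = 0))
  tr <- lib$truth$differential_features
  idx <- vapply(tr$mz, function(z) which.min(abs(fm$feature_mz - z)),
                integer(1))
  hm <- heatmap_matrix(fm$values[, idx], fm$labels)
  expect_lt(max(abs(rowMeans(hm$matrix))), 1e-10)
  expect_equal(unname(apply(hm$matrix, 1, stats::sd)), rep(1, 4))
  # doubling all intensities leaves the standardized matrix unchanged
  hm2 <- heatmap_matrix(fm$values[, idx] * 2, fm$labels)
  expect_equal(hm$matrix, hm2$matrix, tolerance = 1e-12)
  # up-regulated features show a higher mean in the case block
  case_cols <- fm$labels[hm$sample_order] == "AECOPD"
  for (i in seq_len(nrow(tr))) {
    delta <- mean(hm$matrix[i, case_cols]) - mean(hm$matrix[i, !case_cols])
    if (tr$direction[i] == "up") expect_gt(delta, 0) else expect_lt(delta, 0)
  }
  # constant features are dropped with a warning
  expect_warning(heatmap_matrix(cbind(fm$values[, idx[1]], 3), fm$labels),
                 "constant")
})
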
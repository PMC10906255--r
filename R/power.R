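# Pilot-based power and sample-size estimation under FDR control, the
# standard metabolomics design calculation: estimate per-feature
# standardized effects and the null fraction from a pilot, solve for the
# per-test alpha whose expected BH false-discovery proportion matches the
# target, and average two-sample t-test power over the non-null features.

#' Summarize a pilot study for power analysis
#'
#' Per-feature Cohen's d (mean difference over pooled sd on the pilot
#' intensities; use log intensities for log-normal data), the pooled-t
#' p-value histogram estimate of the null fraction pi0 (twice the fraction
#' of p > 0.5, clipped to `[0, 1]`), and optional positive-part
#' James-Stein shrinkage of the d estimates toward 0 to counter the
#' winner's curse of small pilots.
#'
#' @param x Pilot [feature_matrix()] or numeric matrix (samples x
#'   features).
#' @param y Two-class labels; second factor level = case.
#' @param shrink Apply empirical-Bayes shrinkage to the effects?
#' @return List of class `pilot_summary`: `d` (shrunk effects), `d_raw`,
#'   `pi0`, `n_pilot` (per-group counts), `p` (per-feature pooled-t p),
#'   `excluded` (features with zero pooled sd).
#' @export
summarize_pilot <- function(x, y, shrink = TRUE) {
  X <- .fm_values(x)
  f <- .binary_y(y)
  n1 <- sum(f == levels(f)[2]); n0 <- sum(f == levels(f)[1])
  if (min(n0, n1) < 3) stop("at least 3 samples per group are required")
  case <- f == levels(f)[2]
  m1 <- colMeans(X[case, , drop = FALSE])
  m0 <- colMeans(X[!case, , drop = FALSE])
  v1 <- apply(X[case, , drop = FALSE], 2, stats::var)
  v0 <- apply(X[!case, , drop = FALSE], 2, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  excluded <- which(sp == 0)
  if (length(excluded)) {
    warning(length(excluded), " zero-variance feature(s) excluded")
  }
  keep <- sp > 0
  d <- (m1[keep] - m0[keep]) / sp[keep]
  tstat <- d / sqrt(1 / n1 + 1 / n0)
  p <- 2 * stats::pt(abs(tstat), df = n1 + n0 - 2, lower.tail = FALSE)
  pi0 <- min(1, 2 * mean(p > 0.5))
  d_raw <- d
  if (shrink && length(d) > 2) {
    # positive-part James-Stein factor estimated on the non-null set
    # implied by pi0 (the top m1 absolute effects), so that a large null
    # majority does not wash out a sparse signal; counters the winner's
    # curse of small pilots
    se2 <- 1 / n1 + 1 / n0 # sampling variance of d (leading term)
    m1 <- max(1L, round(length(d) * (1 - pi0)))
    dtop <- sort(abs(d), decreasing = TRUE)[seq_len(m1)]
    c_js <- max(0, 1 - max(m1 - 2, 1) * se2 / sum(dtop^2))
    d <- c_js * d
  }
  structure(list(d = d, d_raw = d_raw, pi0 = pi0,
                 n_pilot = c(control = n0, case = n1), p = p,
                 excluded = excluded),
            class = "pilot_summary")
}

#' @export
print.pilot_summary <- function(x, ...) {
  cat("pilot_summary:", length(x$d), "features, pilot n =",
      paste(x$n_pilot, collapse = "/"), "\n")
  cat(sprintf("  pi0 = %.2f | median |d| = %.2f (raw %.2f)\n",
              x$pi0, stats::median(abs(x$d)), stats::median(abs(x$d_raw))))
  invisible(x)
}

# expected BH false-discovery proportion at per-test level alpha:
# pi0*m*alpha / (pi0*m*alpha + sum of non-null powers at alpha)
.expected_fdr <- function(alpha, d_nonnull, n_per_group, m, pi0) {
  pw <- vapply(abs(d_nonnull), function(di) {
    stats::power.t.test(n = n_per_group, delta = di, sd = 1,
                        sig.level = alpha)$power
  }, numeric(1))
  fp <- pi0 * m * alpha
  fp / (fp + sum(pw))
}

#' Predicted average power at a target FDR
#'
#' Solves for the per-test significance level `alpha*` at which the
#' expected Benjamini-Hochberg false-discovery proportion equals the
#' target FDR, given the pilot's null fraction and effect distribution
#' (the `m1 = round(m * (1 - pi0))` largest absolute effects are taken as
#' the non-null set). `alpha*` is capped at the FDR target, so the
#' construction is never anti-conservative. Power is the mean two-sample
#' t-test power over the non-null effects at `alpha*`.
#'
#' @param summary A [summarize_pilot()] result.
#' @param n_per_group Planned per-group sample size (>= 2).
#' @param fdr Target false discovery rate in (0, 1).
#' @return List of class `power_estimate`: `power`, `alpha_star`,
#'   `n_per_group`, `fdr`, `m_nonnull`, `d_nonnull`.
#' @export
predicted_power <- function(summary, n_per_group, fdr = 0.1) {
  stopifnot(inherits(summary, "pilot_summary"),
            n_per_group >= 2, fdr > 0, fdr < 1)
  m <- length(summary$d)
  # non-null count: the pi0 histogram estimate, floored by the number of
  # features already BH-significant in the pilot at q <= 0.25 (histogram
  # pi0 is noisy and upward-biased for small m, and an underestimated
  # non-null count inflates predicted power through selection bias)
  m1 <- round(m * (1 - summary$pi0))
  if (!all(is.na(summary$p))) {
    bh_hits <- sum(stats::p.adjust(summary$p, "BH") <= 0.25, na.rm = TRUE)
    # one or two lenient BH hits can be chance; three or more are taken as
    # direct evidence of the non-null count
    if (bh_hits >= 3) m1 <- max(m1, bh_hits)
  }
  d_abs <- abs(summary$d)
  nz <- d_abs > 0
  if (m1 < 1 || !any(nz)) {
    stop("no non-null features in the pilot; power is undefined")
  }
  d_nonnull <- d_abs[order(d_abs, decreasing = TRUE)][seq_len(min(m1, sum(nz)))]
  d_nonnull <- d_nonnull[d_nonnull > 0]
  g <- function(a) .expected_fdr(a, d_nonnull, n_per_group, m, summary$pi0) - fdr
  lo <- 1e-10
  if (g(fdr) <= 0) {
    alpha_star <- fdr # cap: per-test level never exceeds the FDR target
  } else if (g(lo) >= 0) {
    alpha_star <- lo
  } else {
    alpha_star <- stats::uniroot(g, c(lo, fdr), tol = 1e-12)$root
  }
  pw <- vapply(d_nonnull, function(di) {
    stats::power.t.test(n = n_per_group, delta = di, sd = 1,
                        sig.level = alpha_star)$power
  }, numeric(1))
  structure(list(power = mean(pw), alpha_star = alpha_star,
                 n_per_group = n_per_group, fdr = fdr,
                 m_nonnull = length(d_nonnull), d_nonnull = d_nonnull),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "power_estimate: power %.3f at n = %d/group, FDR %.2f (alpha* = %.2g, %d non-null)\n",
    x$power, x$n_per_group, x$fdr, x$alpha_star, x$m_nonnull))
  invisible(x)
}

#' Power curve over a grid of sample sizes
#'
#' @param summary A [summarize_pilot()] result.
#' @param n_grid Integer vector of per-group sample sizes.
#' @param fdr Target FDR.
#' @return data.frame with `n_per_group`, `power`, `alpha_star`.
#' @export
power_curve <- function(summary, n_grid = c(6, 12, 24, 48, 96), fdr = 0.1) {
  res <- lapply(sort(n_grid), function(n) {
    p <- predicted_power(summary, n, fdr)
    data.frame(n_per_group = n, power = p$power, alpha_star = p$alpha_star)
  })
  do.call(rbind, res)
}

#' Smallest sample size reaching a target power
#'
#' @param summary A [summarize_pilot()] result.
#' @param target_power Required average power.
#' @param fdr Target FDR.
#' @param n_grid Candidate per-group sizes (ascending).
#' @return The smallest n in `n_grid` with predicted power >=
#'   `target_power` (the largest grid value, with a warning, if none).
#' @export
recommend_n <- function(summary, target_power = 0.9, fdr = 0.1,
                        n_grid = c(6, 12, 24, 48, 96, 192)) {
  curve <- power_curve(summary, n_grid, fdr)
  ok <- which(curve$power >= target_power)
  if (!length(ok)) {
    warning("target power not reached on the grid; returning the largest n")
    return(max(curve$n_per_group))
  }
  curve$n_per_group[ok[1]]
}
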
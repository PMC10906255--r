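# Raw spectra -> aligned, normalized feature matrix with QC.

#' Aligned feature-matrix container
#'
#' Samples x features matrix of aligned m/z feature intensities, the
#' central data structure of the pipeline.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param feature_mz Ascending numeric vector of feature m/z (Da), one per
#'   column.
#' @param sample_ids Character vector of sample identifiers, one per row.
#' @param labels Optional group labels, one per row.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_mz, sample_ids, labels = NULL) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(feature_mz),
            nrow(values) == length(sample_ids),
            !is.unsorted(feature_mz),
            all(values >= 0))
  if (!is.null(labels)) stopifnot(length(labels) == nrow(values))
  dimnames(values) <- list(sample_ids, sprintf("%.4f", feature_mz))
  structure(list(values = values, feature_mz = as.numeric(feature_mz),
                 sample_ids = as.character(sample_ids), labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "features, m/z", sprintf("%.2f", min(x$feature_mz)), "-",
      sprintf("%.2f", max(x$feature_mz)), "\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# running minimum / mean over a centred window of k points (k odd),
# edges handled by shrinking the window
.roll_min <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (s in seq(-h, h)) {
    if (s == 0L) next
    idx <- seq_len(n) + s
    ok <- idx >= 1L & idx <= n
    out[ok] <- pmin(out[ok], x[idx[ok]])
  }
  out
}

.roll_mean <- function(x, k) {
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Baseline removal and smoothing of a spectrum
#'
#' Baseline is a rolling minimum over `baseline_window` Da followed by a
#' rolling mean of the same width, subtracted with a floor at zero. The
#' signal is then smoothed with a Savitzky-Golay filter (moving polynomial
#' of degree 2 over `smooth_window` points).
#'
#' @param spectrum An `ldi_spectrum` (list with ascending `mz` and
#'   nonnegative `intensity`).
#' @param baseline_window Width of the baseline windows in Da.
#' @param smooth_window Odd number of points for the degree-2 smoother.
#' @return The spectrum with baseline-subtracted, smoothed intensities.
#' @export
preprocess <- function(spectrum, baseline_window = 5, smooth_window = 7) {
  stopifnot(baseline_window > 0, smooth_window > 0,
            smooth_window %% 2 == 1)
  mz <- spectrum$mz
  y <- spectrum$intensity
  span <- diff(range(mz))
  if (baseline_window >= span) stop("baseline_window larger than spectrum span")
  step <- stats::median(diff(mz))
  k <- max(3L, as.integer(round(baseline_window / step)))
  if (k %% 2L == 0L) k <- k + 1L
  baseline <- .roll_mean(.roll_min(y, k), k)
  y <- pmax(y - baseline, 0)
  if (smooth_window >= 5 && length(y) > smooth_window) {
    y <- signal::sgolayfilt(y, p = 2, n = smooth_window)
    y <- pmax(y, 0)
  }
  spectrum$intensity <- y
  spectrum
}

#' Detect and centroid peaks in a preprocessed spectrum
#'
#' Local maxima whose intensity exceeds `snr_min` times a robust noise
#' estimate (median absolute deviation, scaled by 1.4826, of the detrended
#' signal) are retained. Peak m/z is centroided by Gaussian
#' (log-parabolic) interpolation through the apex and its two neighbours —
#' exact for the Gaussian peak shapes of profile-mode LDI spectra —
#' falling back to the intensity-weighted mean over the apex flanks when a
#' neighbour is nonpositive.
#'
#' @param spectrum A preprocessed `ldi_spectrum`.
#' @param snr_min Minimum signal-to-noise ratio (> 0).
#' @return A data.frame of class `peak_list` with columns `mz`,
#'   `intensity`, `snr`; empty (not an error) for an all-zero spectrum.
#' @export
detect_peaks <- function(spectrum, snr_min = 3) {
  stopifnot(snr_min > 0)
  mz <- spectrum$mz
  y <- spectrum$intensity
  n <- length(y)
  empty <- data.frame(mz = numeric(), intensity = numeric(), snr = numeric())
  class(empty) <- c("peak_list", "data.frame")
  if (all(y == 0)) return(empty)
  # detrend with a wide rolling mean; the noise floor is the larger of the
  # MAD and the upper-quartile deviation of the residual (the latter stays
  # calibrated when rectification piles intensities at zero)
  trend <- .roll_mean(y, min(n - (1 - n %% 2), 501L))
  resid <- y - trend
  noise <- max(stats::mad(resid),
               (stats::quantile(resid, 0.75) - stats::median(resid)) / 0.6745,
               .Machine$double.eps)
  yi <- y[2:(n - 1)]
  apex <- which(yi > y[1:(n - 2)] & yi >= y[3:n]) + 1L
  apex <- apex[y[apex] / noise >= snr_min & y[apex] > 0]
  if (!length(apex)) return(empty)
  res <- lapply(apex, function(i) {
    if (i > 1L && i < n && y[i - 1L] > 0 && y[i + 1L] > 0 &&
        y[i] >= y[i - 1L] && y[i] >= y[i + 1L]) {
      ly <- log(y[(i - 1L):(i + 1L)])
      denom <- ly[1] - 2 * ly[2] + ly[3]
      if (denom < 0) {
        delta <- 0.5 * (ly[1] - ly[3]) / denom
        delta <- max(-0.5, min(0.5, delta))
        return(c(mz[i] + delta * (mz[i + 1L] - mz[i]), y[i]))
      }
    }
    lo <- i
    while (lo > 1L && y[lo - 1L] < y[lo] && y[lo - 1L] > 0.25 * y[i]) lo <- lo - 1L
    hi <- i
    while (hi < n && y[hi + 1L] < y[hi] && y[hi + 1L] > 0.25 * y[i]) hi <- hi + 1L
    w <- lo:hi
    c(sum(mz[w] * y[w]) / sum(y[w]), y[i])
  })
  res <- do.call(rbind, res)
  out <- data.frame(mz = res[, 1], intensity = res[, 2],
                    snr = res[, 2] / noise)
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

# single-linkage clustering of sorted 1-D positions: split where the gap
# between neighbours exceeds tol (exact single linkage cut at height tol)
.cluster_mz <- function(mz_sorted, tol) {
  if (!length(mz_sorted)) return(integer(0))
  cumsum(c(1L, as.integer(diff(mz_sorted) > tol)))
}

#' Align peak lists across samples into a feature matrix
#'
#' Pools all peaks, clusters their m/z by single linkage (clusters split
#' where consecutive sorted m/z differ by more than `tol`), takes the
#' median member m/z as the feature m/z, drops features present in fewer
#' than `min_presence` of samples and imputes missing entries as 0. When a
#' sample contributes several peaks to one cluster the most intense is
#' kept.
#'
#' @param peaklists List of [detect_peaks()] results, one per sample.
#' @param tol Alignment tolerance in Da (single-linkage gap).
#' @param min_presence Minimum fraction of samples a feature must appear in.
#' @param sample_ids Sample identifiers; defaults to list names or S1..Sn.
#' @param labels Optional group labels, passed to the result.
#' @return A [feature_matrix()].
#' @export
align_features <- function(peaklists, tol = 0.2, min_presence = 0.1,
                           sample_ids = NULL, labels = NULL) {
  stopifnot(tol > 0, min_presence > 0, min_presence <= 1)
  if (!length(peaklists)) stop("empty peak list input")
  if (is.null(sample_ids)) {
    sample_ids <- names(peaklists)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_along(peaklists))
  }
  all_mz <- unlist(lapply(peaklists, `[[`, "mz"))
  all_int <- unlist(lapply(peaklists, `[[`, "intensity"))
  all_smp <- rep(seq_along(peaklists),
                 vapply(peaklists, nrow, integer(1)))
  if (!length(all_mz)) stop("no peaks in any sample")
  ord <- order(all_mz)
  all_mz <- all_mz[ord]; all_int <- all_int[ord]; all_smp <- all_smp[ord]
  cl <- .cluster_mz(all_mz, tol)
  nclust <- cl[length(cl)]
  fmz <- as.numeric(tapply(all_mz, cl, stats::median))
  n <- length(peaklists)
  vals <- matrix(0, n, nclust)
  for (j in seq_along(all_mz)) {
    s <- all_smp[j]; k <- cl[j]
    vals[s, k] <- max(vals[s, k], all_int[j])
  }
  presence <- colMeans(vals > 0)
  keep <- presence >= min_presence
  if (!any(keep)) stop("no feature passes the presence filter")
  feature_matrix(vals[, keep, drop = FALSE], fmz[keep], sample_ids, labels)
}

#' Total-ion-current normalization
#'
#' Scales each sample (row) so its total intensity equals the cohort
#' median of the raw totals; relative abundances within a sample are
#' unchanged.
#'
#' @param fm A [feature_matrix()].
#' @return The normalized [feature_matrix()].
#' @export
normalize_tic <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  tot <- rowSums(fm$values)
  if (any(tot <= 0)) {
    stop("zero total intensity for sample(s): ",
         paste(fm$sample_ids[tot <= 0], collapse = ", "))
  }
  target <- stats::median(tot)
  fm$values <- fm$values * (target / tot)
  fm
}

#' Spectral similarity QC scores
#'
#' Cosine similarity of each sample against its group's leave-one-out
#' median profile, plus the fraction of samples scoring above `threshold`
#' (the standard fingerprint-reliability summary).
#'
#' @param fm A [feature_matrix()] with `labels` set.
#' @param threshold QC score threshold (default 0.85).
#' @return List with `scores` (named per-sample cosine similarities) and
#'   `fraction_above` (fraction of samples with score > `threshold`).
#' @export
similarity_scores <- function(fm, threshold = 0.85) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  X <- fm$values
  scores <- vapply(seq_len(nrow(X)), function(i) {
    peers <- which(fm$labels == fm$labels[i])
    peers <- setdiff(peers, i)
    ref <- if (length(peers)) apply(X[peers, , drop = FALSE], 2, stats::median)
      else stop("group of sample ", fm$sample_ids[i], " has a single member")
    v <- X[i, ]
    nv <- sqrt(sum(v^2)); nr <- sqrt(sum(ref^2))
    if (nv == 0) stop("zero-vector sample: ", fm$sample_ids[i])
    if (nr == 0) stop("zero-vector group reference for sample: ",
                      fm$sample_ids[i])
    sum(v * ref) / (nv * nr)
  }, numeric(1))
  names(scores) <- fm$sample_ids
  list(scores = scores, fraction_above = mean(scores > threshold),
       threshold = threshold)
}

#' Per-feature replicate coefficients of variation
#'
#' CV = sd / mean x 100 per feature over technical replicates of one
#' sample. Features with zero mean get `NA` (CV undefined).
#'
#' @param fm A [feature_matrix()] whose rows are replicates of one sample
#'   (at least 3), or a plain numeric matrix replicates x features.
#' @return Numeric vector of CV percentages, one per feature.
#' @export
replicate_cv <- function(fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (nrow(X) < 3) stop("at least 3 replicates are required")
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  cv <- ifelse(m == 0, NA_real_, s / m * 100)
  if (inherits(fm, "feature_matrix")) names(cv) <- colnames(fm$values)
  cv
}
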
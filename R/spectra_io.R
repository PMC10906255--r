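# Reading and writing spectra: a documented CSV dialect (header `mz`, one
# intensity column per sample) and mzML (MS1 profile mode, via mzR).

.apply_window <- function(mz, intensity, window = c(100, 400)) {
  keep <- mz >= window[1] & mz <= window[2]
  list(mz = mz[keep], intensity = intensity[keep])
}

.as_spectrum <- function(mz, intensity, sample_id, window = c(100, 400)) {
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("non-monotone m/z in record '", sample_id, "'")
  }
  w <- .apply_window(mz, intensity, window)
  structure(list(mz = w$mz, intensity = pmax(w$intensity, 0),
                 sample_id = sample_id, metadata = list()),
            class = "ldi_spectrum")
}

#' Read spectra from CSV or mzML
#'
#' The CSV dialect has a header row `mz,<sample_id_1>,...` and one row per
#' grid point; mzML files are read through the mzR library. The 100-400 Da
#' analysis window is applied on read.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"auto"`, `"csv"` or `"mzml"`.
#' @param window m/z window retained on read (Da).
#' @return List of `ldi_spectrum` objects.
#' @export
read_spectra <- function(path, format = c("auto", "csv", "mzml"),
                         window = c(100, 400)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1] != "mz") {
      stop("malformed spectra CSV (first column must be 'mz'): ", path)
    }
    if (ncol(df) < 2) stop("spectra CSV has no sample columns: ", path)
    lapply(names(df)[-1], function(sid) {
      .as_spectrum(df$mz, df[[sid]], sid, window)
    })
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the mzR package")
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    hdr <- mzR::header(h)
    lapply(seq_len(nrow(hdr)), function(i) {
      p <- mzR::peaks(h, i)
      .as_spectrum(p[, 1], p[, 2], sprintf("scan_%d", hdr$acquisitionNum[i]),
                   window)
    })
  }
}

#' Write spectra to CSV or mzML
#'
#' The CSV dialect requires all spectra to share one m/z grid (as produced
#' by the simulator); mzML output writes one MS1 profile-mode scan per
#' spectrum through mzR.
#'
#' @param spectra List of `ldi_spectrum` objects.
#' @param path Output file path.
#' @param format `"auto"`, `"csv"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("auto", "csv", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "csv"
  }
  stopifnot(length(spectra) >= 1)
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  if (format == "csv") {
    mz <- spectra[[1]]$mz
    same <- vapply(spectra, function(s)
      length(s$mz) == length(mz) && all(s$mz == mz), logical(1))
    if (!all(same)) stop("CSV output requires a common m/z grid")
    df <- data.frame(mz = mz, check.names = FALSE)
    for (i in seq_along(spectra)) df[[ids[i]]] <- spectra[[i]]$intensity
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("writing mzML requires the mzR package")
    }
    pks <- lapply(spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
    hdr <- do.call(rbind, lapply(seq_along(spectra), function(i) {
      s <- spectra[[i]]
      data.frame(
        seqNum = i, acquisitionNum = i, msLevel = 1L, polarity = 1L,
        peaksCount = length(s$mz), totIonCurrent = sum(s$intensity),
        retentionTime = i, basePeakMZ = s$mz[which.max(s$intensity)],
        basePeakIntensity = max(s$intensity), collisionEnergy = 0,
        ionisationEnergy = 0, lowMZ = min(s$mz), highMZ = max(s$mz),
        precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
        precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
        mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
        injectionTime = 0, filterString = NA_character_,
        spectrumId = sprintf("scan=%d", i), centroided = FALSE,
        ionMobilityDriftTime = NA_real_,
        isolationWindowTargetMZ = NA_real_,
        isolationWindowLowerOffset = NA_real_,
        isolationWindowUpperOffset = NA_real_,
        scanWindowLowerLimit = min(s$mz), scanWindowUpperLimit = max(s$mz)
      )
    }))
    mzR::writeMSData(pks, path, header = hdr)
  }
  invisible(path)
}

#' Write a feature matrix and its processing-parameter sidecar
#'
#' CSV layout: first column `sample_id`, optional `group`, then one column
#' per feature named by its m/z to 4 decimals. A JSON sidecar stores the
#' processing parameters.
#'
#' @param fm A [feature_matrix()].
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @param params Named list of processing parameters for the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, params = list()) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(sample_id = fm$sample_ids, check.names = FALSE)
  if (!is.null(fm$labels)) df$group <- fm$labels
  df <- cbind(df, as.data.frame(fm$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(c(list(feature_count = ncol(fm$values)), params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- if ("group" %in% names(df)) df$group else NULL
  num <- setdiff(names(df), c("sample_id", "group"))
  feature_matrix(as.matrix(df[, num, drop = FALSE]), as.numeric(num),
                 df$sample_id, labels)
}
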
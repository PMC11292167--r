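#' @include AllClasses.R preprocess.R
NULL

.acc_stats <- function(x) {
  n <- length(x)
  # spectral entropy: Shannon entropy (nats) of the normalized power spectrum,
  # DC excluded; a (near-)constant signal is defined to have entropy 0
  P <- Mod(stats::fft(x))^2
  P <- P[2:(n %/% 2 + 1)]
  tot <- sum(P)
  ent <- if (tot < 1e-12) 0 else {
    p <- P / tot
    p <- p[p > 0]
    -sum(p * log(p))
  }
  c(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
    energy = mean(x^2), entropy = ent)
}

# prominence of each local maximum: height above the higher of the two
# flanking minima (walking out to the nearest higher point or the boundary)
.count_peaks <- function(x, prominence = 0.01) {
  n <- length(x)
  if (n < 3L) return(0L)
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cnt <- 0L
  for (i in idx) {
    j <- i; lmin <- x[i]
    while (j > 1 && x[j] <= x[i]) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    k <- i; rmin <- x[i]
    while (k < n && x[k] <= x[i]) { k <- k + 1L; rmin <- min(rmin, x[k]) }
    if (x[i] - max(lmin, rmin) >= prominence) cnt <- cnt + 1L
  }
  cnt
}

#' Names of the handcrafted per-segment features
#'
#' The frozen, ordered feature set extracted by [extractFeatures()]:
#' accelerometry statistics per axis and magnitude (mean, SD, min, max, mean
#' squared energy, spectral entropy), EDA tonic/phasic summaries (zero-phase
#' low-pass split at 0.05 Hz; phasic peaks counted at 0.01 µS prominence),
#' HRV measures from IBI events inside the window (mean NN, SDNN, RMSSD,
#' pNN50 at the standard 50 ms threshold), and temperature mean/SD.
#'
#' @return Character vector of 35 feature names, in stable order.
#' @export
featureNames <- function() {
  acc <- as.vector(outer(c("mean", "sd", "min", "max", "energy", "entropy"),
                         c("acc_x", "acc_y", "acc_z", "acc_mag"),
                         function(s, a) paste(a, s, sep = "_")))
  c(acc,
    "eda_tonic_mean", "eda_tonic_sd", "eda_phasic_mean", "eda_phasic_sd",
    "eda_phasic_peaks",
    "hrv_mean_nn", "hrv_sdnn", "hrv_rmssd", "hrv_pnn50",
    "temp_mean", "temp_sd")
}

#' Extract the handcrafted feature vector for one segment
#'
#' Operates on a raw (unstandardized) segment. EDA is split into tonic and
#' phasic components with a zero-phase 2nd-order Butterworth low-pass at
#' `eda_cutoff` Hz. HRV features use the IBI events whose times fall inside
#' the segment window; with fewer than 2 events they are flagged missing
#' (`NA`). SDs are sample SDs.
#'
#' @param seg named list of per-channel arrays (one element of a
#'   [SegmentSet-class]).
#' @param fs named per-channel sampling rates.
#' @param ibi an [IBISeries-class] or `NULL`.
#' @param start segment start offset in seconds (for IBI windowing).
#' @param omega segment length in seconds.
#' @param eda_cutoff tonic/phasic low-pass cutoff in Hz (default 0.05).
#' @param peak_prominence phasic peak prominence threshold in µS.
#' @return Named numeric vector in [featureNames()] order (`NA` = missing).
#' @export
extractFeatures <- function(seg, fs, ibi = NULL, start = 0, omega = 512,
                            eda_cutoff = 0.05, peak_prominence = 0.01) {
  out <- stats::setNames(rep(NA_real_, length(featureNames())), featureNames())

  mag <- sqrt(seg$acc_x^2 + seg$acc_y^2 + seg$acc_z^2)
  for (a in c("acc_x", "acc_y", "acc_z")) {
    st <- .acc_stats(seg[[a]])
    out[paste(a, names(st), sep = "_")] <- st
  }
  st <- .acc_stats(mag)
  out[paste("acc_mag", names(st), sep = "_")] <- st

  eda <- seg$eda
  wn <- eda_cutoff / (fs[["eda"]] / 2)
  tonic <- if (wn < 1) {
    bf <- signal::butter(2, wn, type = "low")
    # filter the mean-centered signal to avoid start-up transients
    mean(eda) + as.numeric(signal::filtfilt(bf, eda - mean(eda)))
  } else eda
  phasic <- eda - tonic
  out["eda_tonic_mean"] <- mean(tonic)
  out["eda_tonic_sd"] <- stats::sd(tonic)
  out["eda_phasic_mean"] <- mean(phasic)
  out["eda_phasic_sd"] <- stats::sd(phasic)
  out["eda_phasic_peaks"] <- .count_peaks(phasic, peak_prominence)

  if (!is.null(ibi)) {
    sel <- ibi@event_times >= start & ibi@event_times < start + omega
    nn <- ibi@intervals[sel]
    if (length(nn) >= 2L) {
      out["hrv_mean_nn"] <- mean(nn)
      out["hrv_sdnn"] <- stats::sd(nn)
      d <- diff(nn)
      out["hrv_rmssd"] <- sqrt(mean(d^2))
      out["hrv_pnn50"] <- 100 * mean(abs(d) > 0.050)
    }
  }

  out["temp_mean"] <- mean(seg$temp)
  out["temp_sd"] <- stats::sd(seg$temp)
  out
}

#' Feature matrix for a SegmentSet
#'
#' One row per segment: metadata columns (`session_id`, `subject_id`,
#' `dataset_id`, `start`, `label`) followed by the [featureNames()] columns.
#' IBI series are looked up per session from `sessions`.
#'
#' @param segments a raw [SegmentSet-class].
#' @param sessions optional list of [E4Session-class] objects supplying IBI
#'   (matched by session id).
#' @param ... passed to [extractFeatures()].
#' @return A data.frame; also reports per-column missingness (percent) in the
#'   `"missing_pct"` attribute.
#' @export
extractFeatureMatrix <- function(segments, sessions = NULL, ...) {
  ibi_by <- list()
  for (s in sessions) ibi_by[[sessionId(s)]] <- s@ibi
  info <- segmentInfo(segments)
  rows <- lapply(seq_len(nSegments(segments)), function(i) {
    extractFeatures(segmentData(segments, i), segments@fs,
                    ibi = ibi_by[[info$session_id[i]]],
                    start = info$start[i], omega = segments@omega, ...)
  })
  feats <- as.data.frame(do.call(rbind, rows))
  out <- cbind(info, feats)
  attr(out, "missing_pct") <-
    vapply(feats, function(col) 100 * mean(is.na(col)), numeric(1))
  out
}

#' Mean-impute missing feature values
#'
#' Each missing cell is replaced by the column mean computed over `fit_rows`
#' only (the training rows), so no statistic leaks from validation or test
#' rows. A column entirely missing within `fit_rows` is imputed with 0, with a
#' warning.
#'
#' @param mat a feature matrix from [extractFeatureMatrix()].
#' @param fit_rows integer or logical index of rows to learn the means from;
#'   defaults to all rows.
#' @return `mat` with every [featureNames()] column complete.
#' @export
imputeMissing <- function(mat, fit_rows = seq_len(nrow(mat))) {
  for (col in intersect(featureNames(), names(mat))) {
    m <- mean(mat[fit_rows, col], na.rm = TRUE)
    if (is.nan(m)) {
      warning(sprintf("feature '%s' entirely missing in fitting rows; imputing 0",
                      col))
      m <- 0
    }
    mat[[col]][is.na(mat[[col]])] <- m
  }
  mat
}
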
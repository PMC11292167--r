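#' @include AllClasses.R AllGenerics.R
NULL

# Per-second sample index range [lo, hi] for second s (0-based) at rate fs.
.sec_idx <- function(s, fs) {
  lo <- floor(s * fs) + 1L
  hi <- floor((s + 1) * fs)
  c(lo, hi)
}

#' Detect off-body seconds from EDA and skin temperature
#'
#' A second is flagged off-body iff any EDA sample within it falls below
#' 0.05 µS (loss of skin contact) or above the 100 µS sensor range, or any
#' temperature sample leaves the 30–40 °C physiological range. Decisions are
#' made at 1-second resolution on the EDA/TEMP clock and broadcast to all
#' channels by time interval. `NA` samples do not trigger the rule.
#'
#' @param eda,temp [ChannelSeries-class] for the `eda` and `temp` channels.
#' @param duration timeline length in whole seconds; defaults to the shorter
#'   of the two channels.
#' @param eda_min,eda_max,temp_range thresholds (µS, µS, °C).
#' @return Logical vector over seconds: `TRUE` = off-body.
#' @export
detectOffBody <- function(eda, temp, duration = NULL,
                          eda_min = 0.05, eda_max = 100,
                          temp_range = c(30, 40)) {
  if (is.null(eda) || is.null(temp))
    stop("off-body detection requires both EDA and TEMP channels")
  if (is.null(duration))
    duration <- floor(min(length(eda@values) / eda@fs,
                          length(temp@values) / temp@fs))
  duration <- as.integer(duration)
  off <- logical(duration)
  if (duration == 0L) return(off)
  .sec_any <- function(vals, fs, bad) {
    # per-second any(): pad to whole seconds, fold into a fs x duration matrix
    n <- as.integer(round(duration * fs))
    b <- bad[seq_len(min(n, length(vals)))]
    if (length(b) < n) b <- c(b, rep(FALSE, n - length(b)))
    spl <- factor(floor((seq_len(n) - 1L) / fs), levels = 0:(duration - 1L))
    as.logical(unname(tapply(b, spl, any, default = FALSE)))
  }
  bad_eda <- !is.na(eda@values) & (eda@values < eda_min | eda@values > eda_max)
  bad_tmp <- !is.na(temp@values) &
    (temp@values < temp_range[1] | temp@values > temp_range[2])
  off <- .sec_any(eda@values, eda@fs, bad_eda) |
    .sec_any(temp@values, temp@fs, bad_tmp)
  off
}

#' Enforce a minimum on-body run length
#'
#' On-body runs shorter than `min_run_s` ("unbroken sequences of at least 5
#' minutes") are relabeled off-body; runs of exactly `min_run_s` are kept.
#' Idempotent.
#'
#' @param off logical per-second off-body flags (`TRUE` = off-body).
#' @param min_run_s minimum wear-run duration in seconds (default 300).
#' @return Updated logical flags.
#' @export
enforceMinWearRun <- function(off, min_run_s = 300) {
  if (!length(off)) return(off)
  r <- rle(off)
  short_on <- !r$values & r$lengths < min_run_s
  r$values[short_on] <- TRUE
  inverse.rle(r)
}

#' Arm angle from triaxial acceleration
#'
#' Computes the arm elevation angle on 5-second epochs:
#' `atan(med_z / sqrt(med_x^2 + med_y^2)) * 180 / pi`, where `med_*` are
#' per-epoch medians of each axis. A zero-norm epoch is defined flat (0°).
#' Only complete epochs are emitted.
#'
#' @param acc_x,acc_y,acc_z [ChannelSeries-class] at a common sampling rate.
#' @param epoch_s epoch length in seconds (default 5).
#' @return Numeric vector of per-epoch angles in degrees.
#' @export
computeArmAngle <- function(acc_x, acc_y, acc_z, epoch_s = 5) {
  fs <- acc_x@fs
  stopifnot(acc_y@fs == fs, acc_z@fs == fs)
  n <- min(length(acc_x@values), length(acc_y@values), length(acc_z@values))
  per <- as.integer(round(epoch_s * fs))
  n_ep <- n %/% per
  if (n_ep == 0L) return(numeric(0))
  .med <- function(v) {
    m <- matrix(v[seq_len(n_ep * per)], nrow = per)
    apply(m, 2L, stats::median, na.rm = TRUE)
  }
  mx <- .med(acc_x@values); my <- .med(acc_y@values); mz <- .med(acc_z@values)
  horiz <- sqrt(mx^2 + my^2)
  ang <- atan2(mz, horiz) * 180 / pi
  ang[horiz == 0 & mz == 0] <- 0
  ang[is.na(ang)] <- 0
  ang
}

#' Score sleep and wake over the on-body timeline
#'
#' An on-body period is scored sleep iff it lies within a maximal run of at
#' least `min_sleep_s` seconds in which no successive 5-second-epoch arm-angle
#' change exceeds `angle_thr` degrees. A run is broken by an epoch that is not
#' fully on-body (off-body data are untrustworthy, so sleep runs never bridge
#' an off-body gap). Off-body seconds keep their status; everything else is
#' wake.
#'
#' @param angles per-epoch arm angles from [computeArmAngle()].
#' @param off per-second off-body flags (after [enforceMinWearRun()]).
#' @param epoch_s epoch length used for `angles` (default 5).
#' @param angle_thr maximal angle change within sleep, degrees (default 5).
#' @param min_sleep_s minimal sleep-run duration, seconds (default 300).
#' @return A [StatusTimeline-class] over `length(off)` seconds.
#' @export
detectSleepWake <- function(angles, off, epoch_s = 5, angle_thr = 5,
                            min_sleep_s = 300) {
  n_sec <- length(off)
  st <- ifelse(off, "off_body", "wake")
  n_ep <- length(angles)
  if (n_ep >= 1L) {
    ep_on <- vapply(seq_len(n_ep), function(e) {
      secs <- ((e - 1L) * epoch_s + 1L):min(e * epoch_s, n_sec)
      length(secs) > 0 && !any(off[secs])
    }, logical(1))
    # link[e] = TRUE when epochs e-1 and e belong to the same candidate run
    link <- c(FALSE, abs(diff(angles)) <= angle_thr & ep_on[-n_ep] & ep_on[-1])
    run_id <- cumsum(!link)
    for (id in unique(run_id)) {
      eps <- which(run_id == id)
      eps <- eps[ep_on[eps]]
      if (length(eps) * epoch_s >= min_sleep_s) {
        secs_lo <- (min(eps) - 1L) * epoch_s + 1L
        secs_hi <- min(max(eps) * epoch_s, n_sec)
        idx <- secs_lo:secs_hi
        st[idx][!off[idx]] <- "sleep"
      }
    }
  }
  StatusTimeline(st)
}

#' Per-second status timeline for a session
#'
#' Runs the full rule stack in order: off-body detection (EDA/TEMP
#' thresholds), minimum wear-run enforcement (5 min), then arm-angle
#' sleep/wake scoring. Every second of `[0, duration)` receives exactly one of
#' `off_body`, `sleep`, `wake`.
#'
#' @param session an [E4Session-class] with at least EDA, TEMP and
#'   acceleration channels.
#' @param min_run_s minimum wear run, seconds.
#' @param angle_thr,min_sleep_s sleep-rule parameters.
#' @return A [StatusTimeline-class].
#' @export
statusTimeline <- function(session, min_run_s = 300, angle_thr = 5,
                           min_sleep_s = 300) {
  duration <- floor(sessionDuration(session))
  off <- detectOffBody(session@channels[["eda"]], session@channels[["temp"]],
                       duration = duration)
  off <- enforceMinWearRun(off, min_run_s)
  ang <- computeArmAngle(getChannel(session, "acc_x"),
                         getChannel(session, "acc_y"),
                         getChannel(session, "acc_z"))
  detectSleepWake(ang, off, angle_thr = angle_thr, min_sleep_s = min_sleep_s)
}

#' Number of sliding windows in a span
#'
#' @param L span length, seconds.
#' @param omega window length, seconds.
#' @param step step size, seconds.
#' @return `floor((L - omega) / step) + 1`, or 0 when `L < omega`.
#' @export
segmentCount <- function(L, omega = 512, step = 128) {
  ifelse(L < omega, 0L, as.integer(floor((L - omega) / step) + 1L))
}

#' Slice wake spans into overlapping segments
#'
#' Within each maximal contiguous wake span of length `L >= omega` seconds the
#' sliding window emits `floor((L - omega)/step) + 1` segments starting at
#' `span_start + k * step`; segments never straddle non-wake seconds. Each
#' segment carries the session label and provenance. HR/IBI are not sliced
#' here; they are consumed by the feature extractor directly.
#'
#' @param session an [E4Session-class].
#' @param timeline a [StatusTimeline-class] for the session.
#' @param omega window length in seconds (default 512).
#' @param step step size in seconds (default 128).
#' @return A raw (unstandardized) [SegmentSet-class].
#' @export
segmentWakeSpans <- function(session, timeline, omega = 512, step = 128) {
  st <- status(timeline)
  fs <- vapply(deepChannels(), function(nm) getChannel(session, nm)@fs,
               numeric(1))
  r <- rle(st == "wake")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths    # 0-based span starts
  data <- list(); meta_start <- numeric(0)
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < omega) next
    for (j in 0:((r$lengths[k] - omega) %/% step)) {
      s0 <- starts[k] + j * step
      seg <- lapply(deepChannels(), function(nm) {
        ch <- getChannel(session, nm)
        idx <- (floor(s0 * ch@fs) + 1L):(floor(s0 * ch@fs) + round(omega * ch@fs))
        ch@values[idx]
      })
      names(seg) <- deepChannels()
      data[[length(data) + 1L]] <- seg
      meta_start <- c(meta_start, s0)
    }
  }
  info <- data.frame(session_id = rep(session@session_id, length(data)),
                     subject_id = rep(session@subject_id, length(data)),
                     dataset_id = rep(session@dataset_id, length(data)),
                     start = meta_start,
                     label = rep(session@label, length(data)),
                     stringsAsFactors = FALSE)
  SegmentSet(data, info, omega, fs)
}

#' Preprocess a session into wake segments
#'
#' Convenience wrapper: [statusTimeline()] then [segmentWakeSpans()].
#'
#' @inheritParams segmentWakeSpans
#' @inheritParams statusTimeline
#' @return A raw [SegmentSet-class].
#' @export
preprocessSession <- function(session, omega = 512, step = 128,
                              min_run_s = 300) {
  tl <- statusTimeline(session, min_run_s = min_run_s)
  segmentWakeSpans(session, tl, omega = omega, step = step)
}

#' Fit per-channel standardization statistics
#'
#' Per-channel mean and population SD (divide by n) over all samples of all
#' provided segments. Statistics must be learned only from designated fitting
#' data: for supervised training the target training set, for self-supervised
#' pretraining its aggregation with the unlabeled training data. `scope`
#' records that provenance.
#'
#' @param segments a [SegmentSet-class] (raw).
#' @param scope free-text provenance string.
#' @return A [NormalizationStats-class]; channels whose SD is numerically zero
#'   are listed in its `degenerate` slot.
#' @export
fitNormalization <- function(segments, scope = "unspecified") {
  if (nSegments(segments) == 0L) stop("cannot fit normalization on no segments")
  chs <- names(segments@fs)
  mu <- sd <- stats::setNames(numeric(length(chs)), chs)
  for (ch in chs) {
    v <- unlist(lapply(segments@data, `[[`, ch), use.names = FALSE)
    v <- v[!is.na(v)]
    mu[ch] <- mean(v)
    sd[ch] <- sqrt(mean((v - mu[ch])^2))
  }
  degen <- chs[sd < 1e-8]
  new("NormalizationStats", mean = mu, sd = sd, scope = scope,
      degenerate = degen)
}

#' Standardize segments channel-wise
#'
#' Applies `(x - mean) / max(sd, 1e-8)` per channel with previously fitted
#' statistics; labels and metadata are preserved. A constant channel maps to
#' all zeros via the epsilon guard.
#'
#' @param segments a [SegmentSet-class].
#' @param stats a [NormalizationStats-class] from [fitNormalization()].
#' @return A standardized [SegmentSet-class].
#' @export
standardizeSegments <- function(segments, stats) {
  stopifnot(is(stats, "NormalizationStats"))
  eps <- 1e-8
  segments@data <- lapply(segments@data, function(seg) {
    for (ch in names(segments@fs))
      seg[[ch]] <- (seg[[ch]] - stats@mean[[ch]]) / max(stats@sd[[ch]], eps)
    seg
  })
  segments@standardized <- TRUE
  segments
}
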
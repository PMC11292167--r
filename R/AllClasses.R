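#' @import methods
NULL

#' Channels required by the deep models
#'
#' The multirate transformer consumes the six raw channels of the wristband:
#' triaxial acceleration, blood volume pulse, electrodermal activity and skin
#' temperature. Heart rate and interbeat intervals are derived channels and are
#' consumed only by the handcrafted-feature extractor.
#'
#' @return Character vector of channel names.
#' @export
deepChannels <- function() c("acc_x", "acc_y", "acc_z", "bvp", "eda", "temp")

.known_channels <- c("acc_x", "acc_y", "acc_z", "bvp", "eda", "temp", "hr")

#' ChannelSeries: one uniformly sampled sensor channel
#'
#' A single channel of a wristband session: a numeric vector sampled at a
#' fixed rate `fs` (Hz), anchored at the session start epoch time `t0`
#' (UTC seconds). Missing or corrupt samples are kept as `NA` so sample
#' indices stay aligned to time.
#'
#' @slot name channel identifier, one of acc_x, acc_y, acc_z, bvp, eda,
#'   temp, hr.
#' @slot values numeric samples (may contain `NA` for flagged-missing).
#' @slot fs sampling rate in Hz (> 0).
#' @slot t0 session start, UTC epoch seconds.
#' @export
setClass("ChannelSeries",
  representation(name = "character", values = "numeric",
                 fs = "numeric", t0 = "numeric"))

setValidity("ChannelSeries", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !object@name %in% .known_channels)
    msg <- c(msg, sprintf("unknown channel name '%s'", object@name[1]))
  # fs <= 0 is a content problem surfaced by validateSession(), not a
  # structural one: it must remain representable so findings can be reported
  if (length(object@fs) != 1L || !is.finite(object@fs))
    msg <- c(msg, "fs must be a finite scalar")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a finite epoch time")
  if (length(msg)) msg else TRUE
})

#' Construct a ChannelSeries
#'
#' @param name channel identifier.
#' @param values numeric samples.
#' @param fs sampling rate in Hz.
#' @param t0 session start epoch time in seconds.
#' @return A [ChannelSeries-class] object.
#' @export
ChannelSeries <- function(name, values, fs, t0) {
  new("ChannelSeries", name = name, values = as.numeric(values),
      fs = as.numeric(fs), t0 = as.numeric(t0))
}

#' IBISeries: interbeat-interval events
#'
#' Irregularly timed events marking the time between consecutive ventricular
#' contractions, as emitted by the device's proprietary pulse detection.
#'
#' @slot event_times seconds since session start, strictly increasing.
#' @slot intervals interval durations in seconds, all positive.
#' @export
setClass("IBISeries",
  representation(event_times = "numeric", intervals = "numeric"))

setValidity("IBISeries", function(object) {
  msg <- character()
  if (length(object@event_times) != length(object@intervals))
    msg <- c(msg, "event_times and intervals must have equal length")
  if (length(object@event_times) > 1 && any(diff(object@event_times) <= 0))
    msg <- c(msg, "event_times must be strictly increasing")
  if (any(!is.finite(object@intervals)) || any(object@intervals <= 0))
    msg <- c(msg, "intervals must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an IBISeries
#'
#' @param event_times event offsets in seconds since session start.
#' @param intervals interbeat intervals in seconds.
#' @return An [IBISeries-class] object.
#' @export
IBISeries <- function(event_times, intervals) {
  new("IBISeries", event_times = as.numeric(event_times),
      intervals = as.numeric(intervals))
}

#' E4Session: one subject-device recording
#'
#' The shared session data model: a set of [ChannelSeries-class] at their
#' native rates, an optional [IBISeries-class], identifiers and an optional
#' binary mood-state label (`"acute"` or `"euthymia"`).
#'
#' @slot session_id,subject_id,dataset_id character identifiers.
#' @slot label `"acute"`, `"euthymia"` or `NA_character_`.
#' @slot channels named list of [ChannelSeries-class].
#' @slot ibi an [IBISeries-class] or `NULL`.
#' @export
setClass("E4Session",
  representation(session_id = "character", subject_id = "character",
                 dataset_id = "character", label = "character",
                 channels = "list", ibi = "ANY"))

setValidity("E4Session", function(object) {
  msg <- character()
  if (!all(vapply(object@channels, is, logical(1), "ChannelSeries")))
    msg <- c(msg, "channels must be ChannelSeries objects")
  nm <- vapply(object@channels, function(ch) ch@name, character(1))
  if (length(nm) && !identical(unname(nm), names(object@channels)))
    msg <- c(msg, "channel list names must match channel names")
  if (!object@label %in% c("acute", "euthymia") && !is.na(object@label))
    msg <- c(msg, "label must be 'acute', 'euthymia' or NA")
  if (!is.null(object@ibi) && !is(object@ibi, "IBISeries"))
    msg <- c(msg, "ibi must be an IBISeries or NULL")
  if (length(msg)) msg else TRUE
})

#' Construct an E4Session
#'
#' @param session_id,subject_id,dataset_id identifiers.
#' @param channels named list of [ChannelSeries-class] objects.
#' @param label optional `"acute"` / `"euthymia"`.
#' @param ibi optional [IBISeries-class].
#' @return An [E4Session-class] object.
#' @export
E4Session <- function(session_id, subject_id = session_id,
                      dataset_id = "default", channels = list(),
                      label = NA_character_, ibi = NULL) {
  names(channels) <- vapply(channels, function(ch) ch@name, character(1))
  new("E4Session", session_id = as.character(session_id),
      subject_id = as.character(subject_id),
      dataset_id = as.character(dataset_id),
      label = as.character(label), channels = channels, ibi = ibi)
}

#' StatusTimeline: per-second wear/sleep classification
#'
#' Covers `[0, duration)` of a session at 1-second resolution; every second is
#' exactly one of `off_body`, `sleep`, `wake`.
#'
#' @slot status character vector of per-second statuses.
#' @export
setClass("StatusTimeline", representation(status = "character"))

setValidity("StatusTimeline", function(object) {
  if (!all(object@status %in% c("off_body", "sleep", "wake")))
    "statuses must be off_body/sleep/wake" else TRUE
})

#' Construct a StatusTimeline
#' @param status character vector over session seconds.
#' @return A [StatusTimeline-class] object.
#' @export
StatusTimeline <- function(status) new("StatusTimeline", status = status)

#' SegmentSet: a collection of fixed-length multichannel windows
#'
#' Each segment is an `omega`-second window over the six deep-model channels,
#' with per-channel arrays of length `omega * fs[channel]`, plus provenance
#' metadata (session, subject, dataset, start offset, optional label).
#'
#' @slot omega window length in seconds.
#' @slot fs named numeric: per-channel sampling rate.
#' @slot data list of segments; each a named list of numeric arrays.
#' @slot info data.frame with columns session_id, subject_id, dataset_id,
#'   start, label — one row per segment.
#' @slot standardized logical: whether channels have been standardized.
#' @export
setClass("SegmentSet",
  representation(omega = "numeric", fs = "numeric", data = "list",
                 info = "data.frame", standardized = "logical"))

setValidity("SegmentSet", function(object) {
  msg <- character()
  if (nrow(object@info) != length(object@data))
    msg <- c(msg, "info rows must match number of segments")
  need <- c("session_id", "subject_id", "dataset_id", "start", "label")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, "info must have session_id/subject_id/dataset_id/start/label")
  if (length(object@data)) {
    seg <- object@data[[1]]
    for (ch in names(object@fs)) {
      if (is.null(seg[[ch]]))
        msg <- c(msg, sprintf("segment missing channel %s", ch))
      else if (length(seg[[ch]]) != round(object@omega * object@fs[[ch]]))
        msg <- c(msg, sprintf("channel %s length != omega * fs", ch))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentSet
#'
#' @param data list of segments (named lists of per-channel numeric arrays).
#' @param info per-segment metadata data.frame.
#' @param omega window length in seconds.
#' @param fs named per-channel sampling rates.
#' @param standardized whether segments are already standardized.
#' @return A [SegmentSet-class] object.
#' @export
SegmentSet <- function(data, info, omega, fs, standardized = FALSE) {
  rownames(info) <- NULL
  new("SegmentSet", omega = as.numeric(omega), fs = fs, data = data,
      info = info, standardized = standardized)
}

#' NormalizationStats: per-channel standardization statistics
#'
#' Per-channel mean and population SD learned from a designated fitting
#' collection only; `scope` records provenance so leakage can be audited.
#'
#' @slot mean,sd named numeric vectors.
#' @slot scope free-text provenance (e.g. "target-train" or "ssl-train").
#' @slot degenerate names of channels whose SD was (numerically) zero.
#' @export
setClass("NormalizationStats",
  representation(mean = "numeric", sd = "numeric", scope = "character",
                 degenerate = "character"))

setValidity("NormalizationStats", function(object) {
  if (!identical(names(object@mean), names(object@sd)))
    return("mean and sd must be named identically")
  if (any(object@sd < 0)) return("SD must be nonnegative")
  TRUE
})
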
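#' @include AllClasses.R
NULL

#' Accessors for session and segment objects
#'
#' Small accessor generics so downstream code never reaches into slots:
#' `sessionId()`, `subjectId()`, `datasetId()`, `sessionLabel()`,
#' `channelNames()`, `getChannel()`, `sessionDuration()`, `status()`,
#' `nSegments()`, `segmentInfo()`, `segmentData()`.
#'
#' @param x an [E4Session-class], [StatusTimeline-class] or
#'   [SegmentSet-class] object.
#' @param name a channel name for `getChannel()`.
#' @param i segment index for `segmentData()`.
#' @return The corresponding field: identifiers as character scalars,
#'   `getChannel()` a [ChannelSeries-class], `sessionDuration()` seconds,
#'   `status()` a character vector, `segmentInfo()` a data.frame,
#'   `segmentData()` a named list of per-channel arrays.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))
#' @rdname accessors
#' @export
setGeneric("sessionLabel", function(x) standardGeneric("sessionLabel"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))
#' @rdname accessors
#' @export
setGeneric("status", function(x) standardGeneric("status"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("segmentInfo", function(x) standardGeneric("segmentInfo"))
#' @rdname accessors
#' @export
setGeneric("segmentData", function(x, i) standardGeneric("segmentData"))

#' @rdname accessors
setMethod("sessionId", "E4Session", function(x) x@session_id)
#' @rdname accessors
setMethod("subjectId", "E4Session", function(x) x@subject_id)
#' @rdname accessors
setMethod("datasetId", "E4Session", function(x) x@dataset_id)
#' @rdname accessors
setMethod("sessionLabel", "E4Session", function(x) x@label)
#' @rdname accessors
setMethod("channelNames", "E4Session", function(x) names(x@channels))
#' @rdname accessors
setMethod("getChannel", "E4Session", function(x, name) {
  if (is.null(x@channels[[name]]))
    stop(sprintf("channel '%s' absent from session %s", name, x@session_id))
  x@channels[[name]]
})

#' @rdname accessors
setMethod("sessionDuration", "E4Session", function(x) {
  if (!length(x@channels)) return(0)
  min(vapply(x@channels, function(ch) length(ch@values) / ch@fs, numeric(1)))
})

#' @rdname accessors
setMethod("status", "StatusTimeline", function(x) x@status)
#' @rdname accessors
setMethod("sessionDuration", "StatusTimeline", function(x) length(x@status))

#' @rdname accessors
setMethod("nSegments", "SegmentSet", function(x) length(x@data))
#' @rdname accessors
setMethod("segmentInfo", "SegmentSet", function(x) x@info)
#' @rdname accessors
setMethod("segmentData", "SegmentSet", function(x, i) x@data[[i]])

#' Subset a SegmentSet
#'
#' @param x a [SegmentSet-class].
#' @param i integer or logical index over segments.
#' @param j,...,drop ignored.
#' @return A [SegmentSet-class] with the selected segments.
#' @export
setMethod("[", "SegmentSet", function(x, i, j, ..., drop = FALSE) {
  SegmentSet(x@data[i], x@info[i, , drop = FALSE], x@omega, x@fs,
             standardized = x@standardized)
})

#' Concatenate SegmentSets
#' @param x,... [SegmentSet-class] objects with identical omega/fs.
#' @return A combined [SegmentSet-class].
#' @export
setMethod("c", "SegmentSet", function(x, ...) {
  more <- list(...)
  for (y in more) {
    stopifnot(identical(x@omega, y@omega), identical(x@fs, y@fs),
              identical(x@standardized, y@standardized))
    x@data <- c(x@data, y@data)
    x@info <- rbind(x@info, y@info)
  }
  rownames(x@info) <- NULL
  validObject(x)
  x
})

setMethod("show", "ChannelSeries", function(object) {
  cat(sprintf("ChannelSeries '%s': %d samples @ %g Hz (%.1f s), t0=%.0f\n",
              object@name, length(object@values), object@fs,
              length(object@values) / object@fs, object@t0))
})

setMethod("show", "E4Session", function(object) {
  cat(sprintf("E4Session %s (subject %s, dataset %s, label %s)\n",
              object@session_id, object@subject_id, object@dataset_id,
              ifelse(is.na(object@label), "<none>", object@label)))
  cat(sprintf("  channels: %s\n", paste(names(object@channels), collapse = ", ")))
  cat(sprintf("  duration: %.1f s; IBI events: %d\n", sessionDuration(object),
              if (is.null(object@ibi)) 0L else length(object@ibi@event_times)))
})

setMethod("show", "StatusTimeline", function(object) {
  tb <- table(factor(object@status, levels = c("wake", "sleep", "off_body")))
  cat(sprintf("StatusTimeline over %d s: wake %d, sleep %d, off_body %d\n",
              length(object@status), tb[["wake"]], tb[["sleep"]],
              tb[["off_body"]]))
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet: %d segments of %g s (%s)\n", length(object@data),
              object@omega,
              if (object@standardized) "standardized" else "raw"))
  if (nrow(object@info)) {
    cat(sprintf("  subjects: %d; labels: %s\n",
                length(unique(object@info$subject_id)),
                paste(names(table(object@info$label, useNA = "ifany")),
                      collapse = "/")))
  }
})

setMethod("show", "NormalizationStats", function(object) {
  cat(sprintf("NormalizationStats (scope: %s)\n", object@scope))
  print(round(rbind(mean = object@mean, sd = object@sd), 4))
  if (length(object@degenerate))
    cat("  degenerate channels:", paste(object@degenerate, collapse = ", "), "\n")
})
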
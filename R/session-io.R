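#' @include AllClasses.R
NULL

# Export dialect (mirrors the de-facto device export):
#   ACC.csv  — 3 columns (x,y,z); row 1 = start epoch (repeated), row 2 = fs,
#              then one sample per line.
#   BVP.csv, EDA.csv, TEMP.csv, HR.csv — 1 column, same header layout.
#   IBI.csv  — row 1 = "<t0>, IBI", then rows "offset,interval" (seconds).
#   META.csv — key,value rows carrying session/subject/dataset ids and label
#              (an extension of the dialect; absent META falls back to the
#              directory name and no label).
.channel_files <- c(acc = "ACC.csv", bvp = "BVP.csv", eda = "EDA.csv",
                    temp = "TEMP.csv", hr = "HR.csv")

.fmt <- function(x) {
  out <- sprintf("%.6f", x)
  out[!is.finite(x)] <- "nan"
  out
}

.parse_num <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[is.nan(v)] <- NA_real_
  v
}

.read_channel_file <- function(path, ncol_expect) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop(sprintf("dialect error: %s lacks the two header rows", basename(path)))
  hdr1 <- .parse_num(strsplit(lines[1L], ",")[[1]])
  hdr2 <- .parse_num(strsplit(lines[2L], ",")[[1]])
  if (any(is.na(hdr1)) || any(is.na(hdr2)) || length(hdr1) < 1L)
    stop(sprintf("dialect error: malformed header in %s", basename(path)))
  if (any(hdr2 <= 0))
    stop(sprintf("dialect error: nonpositive sampling rate in %s",
                 basename(path)))
  body <- lines[-(1:2)]
  if (length(body)) {
    cells <- strsplit(body, ",")
    nc <- lengths(cells)
    if (any(nc != nc[1L]))
      stop(sprintf("dialect error: ragged rows in %s", basename(path)))
    vals <- matrix(.parse_num(unlist(cells)), ncol = nc[1L], byrow = TRUE)
  } else {
    vals <- matrix(numeric(0), ncol = max(1L, length(hdr1)))
  }
  if (!is.null(ncol_expect) && ncol(vals) != ncol_expect)
    stop(sprintf("dialect error: expected %d columns in %s", ncol_expect,
                 basename(path)))
  list(t0 = hdr1[1L], fs = hdr2[1L], values = vals)
}

#' Read an E4-style session export
#'
#' Reads the per-channel CSV export dialect (one file per sensor, first row =
#' start epoch, second row = sampling rate, then one sample per line; ACC has
#' three columns; IBI is an event file of `offset,interval` pairs) into an
#' [E4Session-class]. Missing optional files (HR, IBI) yield absent channels;
#' missing required files are an error.
#'
#' @param path directory containing the export.
#' @param strict if `TRUE`, any [validateSession()] finding is promoted to an
#'   error after reading.
#' @return An [E4Session-class].
#' @export
readE4Session <- function(path, strict = FALSE) {
  need <- c("ACC.csv", "BVP.csv", "EDA.csv", "TEMP.csv")
  have <- file.exists(file.path(path, need))
  if (!all(have))
    stop(sprintf("session export at %s is missing: %s", path,
                 paste(need[!have], collapse = ", ")))

  meta <- list(session_id = basename(normalizePath(path, mustWork = FALSE)),
               subject_id = NA_character_, dataset_id = "default",
               label = NA_character_)
  mpath <- file.path(path, "META.csv")
  if (file.exists(mpath)) {
    m <- utils::read.csv(mpath, header = FALSE,
                         col.names = c("key", "value"),
                         colClasses = "character")
    for (i in seq_len(nrow(m))) meta[[m$key[i]]] <- m$value[i]
  }
  if (is.na(meta$subject_id)) meta$subject_id <- meta$session_id
  if (identical(meta$label, "")) meta$label <- NA_character_

  channels <- list()
  acc <- .read_channel_file(file.path(path, "ACC.csv"), 3L)
  for (k in 1:3) {
    nm <- c("acc_x", "acc_y", "acc_z")[k]
    channels[[nm]] <- ChannelSeries(nm, acc$values[, k], acc$fs, acc$t0)
  }
  for (nm in c("bvp", "eda", "temp", "hr")) {
    f <- file.path(path, .channel_files[[nm]])
    if (!file.exists(f)) next
    ch <- .read_channel_file(f, 1L)
    channels[[nm]] <- ChannelSeries(nm, ch$values[, 1], ch$fs, ch$t0)
  }

  ibi <- NULL
  ipath <- file.path(path, "IBI.csv")
  if (file.exists(ipath)) {
    lines <- readLines(ipath)
    if (!length(lines) || is.na(.parse_num(strsplit(lines[1L], ",")[[1]][1])))
      stop("dialect error: malformed IBI header")
    if (length(lines) > 1L) {
      cells <- strsplit(lines[-1L], ",")
      et <- .parse_num(vapply(cells, `[`, character(1), 1L))
      iv <- .parse_num(vapply(cells, `[`, character(1), 2L))
      ibi <- IBISeries(et, iv)   # validity rejects non-monotone events
    }
  }

  sess <- E4Session(meta$session_id, meta$subject_id, meta$dataset_id,
                    channels = channels, label = meta$label, ibi = ibi)
  if (strict) {
    findings <- validateSession(sess)
    if (length(findings))
      stop("session failed strict validation: ",
           paste(findings, collapse = "; "))
  }
  sess
}

#' Write an E4-style session export
#'
#' Writes an [E4Session-class] back to the per-channel CSV dialect read by
#' [readE4Session()]; the round trip is lossless up to float formatting, and a
#' write-read-write cycle is byte-identical.
#'
#' @param session an [E4Session-class] with at least the six deep-model
#'   channels' acceleration/BVP/EDA/TEMP data.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeE4Session <- function(session, path) {
  stopifnot(is(session, "E4Session"))
  if (!length(session@channels)) stop("cannot write a session with no channels")
  if (!all(c("acc_x", "acc_y", "acc_z") %in% names(session@channels)))
    stop("session lacks triaxial acceleration")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop(sprintf("cannot create directory %s", path))

  ax <- session@channels[["acc_x"]]; ay <- session@channels[["acc_y"]]
  az <- session@channels[["acc_z"]]
  hdr <- c(paste(.fmt(rep(ax@t0, 3)), collapse = ","),
           paste(sprintf("%g", rep(ax@fs, 3)), collapse = ","))
  body <- paste(.fmt(ax@values), .fmt(ay@values), .fmt(az@values), sep = ",")
  writeLines(c(hdr, body), file.path(path, "ACC.csv"))

  for (nm in c("bvp", "eda", "temp", "hr")) {
    ch <- session@channels[[nm]]
    if (is.null(ch)) next
    writeLines(c(.fmt(ch@t0), sprintf("%g", ch@fs), .fmt(ch@values)),
               file.path(path, .channel_files[[nm]]))
  }

  if (!is.null(session@ibi)) {
    lines <- c(paste0(.fmt(ax@t0), ", IBI"),
               paste(.fmt(session@ibi@event_times),
                     .fmt(session@ibi@intervals), sep = ","))
    writeLines(lines, file.path(path, "IBI.csv"))
  }

  meta <- c(session_id = session@session_id, subject_id = session@subject_id,
            dataset_id = session@dataset_id,
            label = ifelse(is.na(session@label), "", session@label))
  writeLines(paste(names(meta), meta, sep = ","), file.path(path, "META.csv"))
  invisible(path)
}

#' Validate a session against the data-model invariants
#'
#' Returns a (possibly empty) character vector of findings; never raises on
#' content. Checked: positive sampling rates, presence of the six deep-model
#' channels, agreement of channel durations within one sample period of the
#' slowest channel, IBI monotonicity/positivity, shared `t0`.
#'
#' @param session an [E4Session-class].
#' @return Character vector of human-readable findings (empty if well formed).
#' @export
validateSession <- function(session) {
  findings <- character()
  chs <- session@channels
  for (nm in names(chs)) {
    if (!is.finite(chs[[nm]]@fs) || chs[[nm]]@fs <= 0)
      findings <- c(findings, sprintf("%s: nonpositive sampling rate", nm))
  }
  missing <- setdiff(deepChannels(), names(chs))
  if (length(missing))
    findings <- c(findings, sprintf("missing required channels: %s",
                                    paste(missing, collapse = ", ")))
  ok <- names(chs)[vapply(chs, function(ch) is.finite(ch@fs) && ch@fs > 0,
                          logical(1))]
  if (length(ok) > 1L) {
    dur <- vapply(chs[ok], function(ch) length(ch@values) / ch@fs, numeric(1))
    tol <- 1 / min(vapply(chs[ok], function(ch) ch@fs, numeric(1)))
    if (max(dur) - min(dur) > tol)
      findings <- c(findings,
                    sprintf("channel duration mismatch: %.2f s spread (%s)",
                            max(dur) - min(dur),
                            paste(sprintf("%s=%.1fs", ok, dur),
                                  collapse = ", ")))
    t0 <- vapply(chs[ok], function(ch) ch@t0, numeric(1))
    if (length(unique(t0)) > 1L)
      findings <- c(findings, "channels do not share a start time")
  }
  if (!is.null(session@ibi)) {
    et <- session@ibi@event_times
    if (length(et) > 1L && any(diff(et) <= 0))
      findings <- c(findings, "IBI event times not strictly increasing")
    if (any(session@ibi@intervals <= 0, na.rm = TRUE))
      findings <- c(findings, "nonpositive IBI intervals")
  }
  findings
}
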
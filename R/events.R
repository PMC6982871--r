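# Raw binary-sensor event streams: one timestamped state change per record
# (timestamp, sensor id, state, inhabitant). Files are one record per line,
# tab- or comma-delimited, no header; timestamps are ISO-8601
# ("2017-11-10 08:00:01", "T" separator accepted) with a day/month fallback
# ("10/11/2017 08:00:01"). All times are handled in UTC.

.TZ <- "UTC"

#' Construct a sensor event table
#'
#' @param timestamp `POSIXct` vector (or ISO strings) with seconds precision.
#' @param sensor_id Character vector of sensor identifiers.
#' @param state Character vector of sensor states.
#' @param inhabitant Inhabitant name(s); recycled.
#' @param registry Optional `sensor_registry`; when given, events are
#'   validated against it.
#' @return A `sensor_events` data frame sorted by timestamp (stable for ties).
#' @export
sensor_events <- function(timestamp, sensor_id, state,
                          inhabitant = "Resident", registry = NULL) {
  if (is.character(timestamp)) timestamp <- parse_timestamps(timestamp)
  ev <- data.frame(
    timestamp = as.POSIXct(timestamp, tz = .TZ),
    sensor_id = as.character(sensor_id),
    state = as.character(state),
    inhabitant = rep_len(as.character(inhabitant), length(sensor_id)),
    stringsAsFactors = FALSE
  )
  ord <- order(ev$timestamp, seq_len(nrow(ev))) # index tiebreak => stable
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  ev <- structure(ev, class = c("sensor_events", "data.frame"))
  if (!is.null(registry)) validate_events(ev, registry)
  ev
}

#' Validate events against a sensor registry
#'
#' Checks that every event's sensor id exists in the registry and that its
#' state is one of the two states registered for that sensor.
#'
#' @param events A `sensor_events` data frame.
#' @param registry A `sensor_registry`.
#' @return `events`, invisibly, if valid; otherwise an error naming the
#'   offending sensor id or state.
#' @export
validate_events <- function(events, registry) {
  unknown <- setdiff(unique(events$sensor_id), registry$sensor_id)
  if (length(unknown) > 0) {
    stop("validation error: unknown sensor id(s): ", paste(unknown, collapse = ", "))
  }
  i <- match(events$sensor_id, registry$sensor_id)
  pairs <- strsplit(registry$states[i], "/", fixed = TRUE)
  ok <- mapply(function(s, p) s %in% p, events$state, pairs)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("validation error: state '", events$state[bad], "' not registered for sensor ",
         events$sensor_id[bad])
  }
  invisible(events)
}

#' Read a raw event stream
#'
#' @param source Path to an event file, or a literal string containing the
#'   records (detected by an embedded newline).
#' @param registry A `sensor_registry` used to validate ids and states.
#' @return A `sensor_events` data frame, sorted ascending by timestamp with
#'   stable order for simultaneous events.
#' @export
read_event_stream <- function(source, registry) {
  is_literal <- length(source) == 1 &&
    (grepl("[\n\t]", source) || (grepl(",", source) && !file.exists(source)))
  lines <- if (is_literal) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(source, encoding = "UTF-8")
  }
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(sensor_events(as.POSIXct(character(), tz = .TZ), character(), character()))
  }
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1]
    stop("format error at line ", lineno[bad], ": expected 4 fields, got ", nf[bad])
  }
  field <- function(k) trimws(vapply(parts, `[[`, "", k))
  ts_raw <- field(1)
  ts <- parse_timestamps(ts_raw)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("format error at line ", lineno[bad], ": unparseable timestamp '", ts_raw[bad], "'")
  }
  sensor_events(ts, field(2), field(3), field(4), registry = registry)
}

#' Write an event stream in the raw file dialect
#'
#' Tab-delimited, one record per line, ISO-8601 timestamps; re-readable by
#' [read_event_stream()].
#'
#' @param events A `sensor_events` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_stream <- function(events, path) {
  lines <- paste(format(events$timestamp, "%Y-%m-%d %H:%M:%S", tz = .TZ),
                 events$sensor_id, events$state, events$inhabitant, sep = "\t")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

parse_timestamps <- function(x) {
  x <- trimws(x)
  x <- gsub("T", " ", x, fixed = TRUE)
  ts <- as.POSIXct(x, tz = .TZ, format = "%Y-%m-%d %H:%M:%S")
  dm <- is.na(ts)
  if (any(dm)) { # day/month fallback, e.g. "10/11/2017 08:00:01"
    ts[dm] <- as.POSIXct(x[dm], tz = .TZ, format = "%d/%m/%Y %H:%M:%S")
  }
  ts
}

#' Read activity annotations
#'
#' Annotations are labelled time intervals: a CSV with columns `class_id`,
#' `start`, `end`.
#'
#' @param source Path or literal CSV string.
#' @return An `activity_annotations` data frame with `POSIXct` bounds,
#'   sorted by start time. Errors if any interval has `start >= end`.
#' @export
read_annotations <- function(source) {
  df <- read_table_source(source)
  required <- c("class_id", "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("annotation format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  annotations(df$class_id, df$start, df$end)
}

#' Construct activity annotations
#'
#' @param class_id Activity class labels.
#' @param start,end Interval bounds (`POSIXct` or parseable strings).
#' @return An `activity_annotations` data frame sorted by `start`.
#' @export
annotations <- function(class_id, start, end) {
  if (is.character(start)) start <- parse_timestamps(start)
  if (is.character(end)) end <- parse_timestamps(end)
  df <- data.frame(class_id = as.character(class_id),
                   start = as.POSIXct(start, tz = .TZ),
                   end = as.POSIXct(end, tz = .TZ),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("annotation error: start must precede end")
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("activity_annotations", "data.frame"))
}

#' Write annotations to CSV
#' @param ann An `activity_annotations` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  out <- data.frame(class_id = ann$class_id,
                    start = format(ann$start, "%Y-%m-%d %H:%M:%S", tz = .TZ),
                    end = format(ann$end, "%Y-%m-%d %H:%M:%S", tz = .TZ))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
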
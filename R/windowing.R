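# Windowing and feature extraction. Event streams are tiled into fixed-width
# non-overlapping windows (default 30 s) with half-open membership
# [start, end); each window becomes one instance: 30 per-sensor components in
# registry order plus a single time-routine component, all in [0, 1].

.ROUTINES <- c("Morning", "Afternoon", "Evening")
.ROUTINE_CODE <- c(Morning = 0, Afternoon = 0.5, Evening = 1)

#' Time routine of a timestamp
#'
#' Coarse time-of-day partition used both as a feature and to partition the
#' base models: Morning is \[06:00, 12:00), Afternoon \[12:00, 18:00) and
#' Evening \[18:00, 06:00) (night hours fold into Evening).
#'
#' @param t `POSIXct` vector (or parseable strings).
#' @return Character vector in `c("Morning", "Afternoon", "Evening")`.
#' @examples
#' routine_of(as.POSIXct("2017-11-10 08:00:00", tz = "UTC"))
#' @export
routine_of <- function(t) {
  if (is.character(t)) t <- parse_timestamps(t)
  lt <- as.POSIXlt(t, tz = .TZ)
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  ifelse(h >= 6 & h < 12, "Morning", ifelse(h >= 12 & h < 18, "Afternoon", "Evening"))
}

#' Numeric encoding of a routine tag
#'
#' Scalar code `Morning = 0`, `Afternoon = 0.5`, `Evening = 1`, keeping the
#' routine feature inside \[0, 1\] and the total dimensionality at
#' one-per-sensor plus one.
#'
#' @param tag Character vector of routine tags.
#' @return Numeric vector in \{0, 0.5, 1\}.
#' @export
routine_code <- function(tag) {
  unname(.ROUTINE_CODE[match(tag, names(.ROUTINE_CODE))])
}

#' Segment an event stream into fixed windows
#'
#' Tiles `[origin, max(timestamp)]` with consecutive `window_seconds`-wide
#' half-open windows and assigns every event to exactly one window. Windows
#' are emitted for the full tiling (including empty ones) so that the grid is
#' reproducible; an empty event stream yields zero windows.
#'
#' @param events A `sensor_events` data frame (sorted; as returned by the
#'   readers/constructors).
#' @param window_seconds Window width in seconds (default 30).
#' @param origin Grid origin (`POSIXct`); defaults to midnight of the first
#'   event's day. Events before `origin` are an error.
#' @return A list with `windows` (data frame: `start`, `end`, `routine`,
#'   `n_events`) and `assignment` (integer window index per event row).
#' @export
segment_events <- function(events, window_seconds = 30, origin = NULL) {
  stopifnot(window_seconds > 0)
  n <- nrow(events)
  if (n == 0) {
    win <- data.frame(start = as.POSIXct(character(), tz = .TZ),
                      end = as.POSIXct(character(), tz = .TZ),
                      routine = character(), n_events = integer())
    return(list(windows = win, assignment = integer()))
  }
  if (is.null(origin)) origin <- as.POSIXct(trunc(min(events$timestamp), "days"), tz = .TZ)
  off <- as.numeric(difftime(events$timestamp, origin, units = "secs"))
  if (any(off < 0)) stop("events precede the window origin")
  idx <- floor(off / window_seconds) + 1L
  n_win <- max(idx)
  starts <- origin + (seq_len(n_win) - 1L) * window_seconds
  win <- data.frame(start = starts,
                    end = starts + window_seconds,
                    routine = routine_of(starts),
                    n_events = tabulate(idx, nbins = n_win),
                    stringsAsFactors = FALSE)
  list(windows = win, assignment = as.integer(idx))
}

#' Extract per-window feature vectors
#'
#' One row per window: one component per registry sensor (in registry order)
#' plus the routine code, so `ncol = nrow(registry) + 1`. In `"indicator"`
#' mode (default) a sensor component is 1 if that sensor emitted at least one
#' event within the window, else 0; `"fraction"` mode uses the fraction of
#' the window's events contributed by that sensor, a soft activation that
#' also stays in \[0, 1\].
#'
#' @param events A `sensor_events` data frame.
#' @param segmentation Result of [segment_events()] on `events`.
#' @param registry A `sensor_registry`.
#' @param mode `"indicator"` or `"fraction"`.
#' @return Numeric matrix (windows x features) with sensor-id column names
#'   plus `"routine"`.
#' @export
extract_features <- function(events, segmentation, registry,
                             mode = c("indicator", "fraction")) {
  mode <- match.arg(mode)
  win <- segmentation$windows
  n_win <- nrow(win)
  ids <- registry$sensor_id
  X <- matrix(0, nrow = n_win, ncol = length(ids) + 1L,
              dimnames = list(NULL, c(ids, "routine")))
  if (n_win == 0) return(X)
  if (nrow(events) > 0) {
    s <- match(events$sensor_id, ids)
    if (anyNA(s)) stop("validation error: event sensor id absent from registry")
    counts <- matrix(0, nrow = n_win, ncol = length(ids))
    for (k in seq_along(s)) {
      counts[segmentation$assignment[k], s[k]] <- counts[segmentation$assignment[k], s[k]] + 1
    }
    if (mode == "indicator") {
      X[, seq_along(ids)] <- (counts > 0) + 0
    } else {
      tot <- pmax(rowSums(counts), 1)
      X[, seq_along(ids)] <- counts / tot
    }
  }
  X[, "routine"] <- routine_code(win$routine)
  X
}

#' Label windows from activity annotations
#'
#' Assigns to each window the class of the annotation with maximal temporal
#' overlap; ties go to the earlier-starting annotation. Windows overlapping
#' no annotation are discarded from the labelled set and reported.
#'
#' @param segmentation Result of [segment_events()].
#' @param X Feature matrix from [extract_features()] (same window order).
#' @param ann An `activity_annotations` data frame.
#' @return A `har_dataset`: list with `X` (labelled rows only), `y`
#'   (character labels), `windows` (the labelled windows) and `discarded`
#'   (integer indices of unlabelled windows).
#' @export
label_windows <- function(segmentation, X, ann) {
  win <- segmentation$windows
  n <- nrow(win)
  y <- rep(NA_character_, n)
  if (n > 0 && nrow(ann) > 0) {
    ws <- as.numeric(win$start); we <- as.numeric(win$end)
    as_ <- as.numeric(ann$start); ae <- as.numeric(ann$end)
    for (i in seq_len(n)) {
      ov <- pmin(we[i], ae) - pmax(ws[i], as_)
      ov[ov < 0] <- 0
      if (any(ov > 0)) {
        best <- which(ov == max(ov))[1] # ann sorted by start => earlier wins ties
        y[i] <- ann$class_id[best]
      }
    }
  }
  keep <- !is.na(y)
  har_dataset(X[keep, , drop = FALSE], y[keep],
              windows = win[keep, , drop = FALSE],
              discarded = which(!keep))
}

#' Construct a labelled dataset
#'
#' @param X Numeric feature matrix, one row per instance, values in \[0, 1\].
#' @param y Character (or factor) label vector, one per row of `X`.
#' @param windows Optional window metadata (kept as-is).
#' @param discarded Optional indices of windows dropped during labelling.
#' @return A `har_dataset` list with elements `X`, `y`, `n`, `d`.
#' @export
har_dataset <- function(X, y, windows = NULL, discarded = integer()) {
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  structure(list(X = X, y = y, n = nrow(X), d = ncol(X),
                 windows = windows, discarded = discarded),
            class = "har_dataset")
}

#' @export
print.har_dataset <- function(x, ...) {
  cat("<har_dataset> ", x$n, " instances, ", x$d, " features, ",
      length(unique(x$y)), " classes\n", sep = "")
  invisible(x)
}

# Row subset of a dataset.
dataset_slice <- function(data, idx) {
  har_dataset(data$X[idx, , drop = FALSE], data$y[idx],
              windows = if (!is.null(data$windows)) data$windows[idx, , drop = FALSE])
}

#' End-to-end feature preparation from raw events
#'
#' Convenience wrapper: segment, extract features, label.
#'
#' @inheritParams segment_events
#' @inheritParams extract_features
#' @param ann An `activity_annotations` data frame.
#' @param registry A `sensor_registry`.
#' @return A `har_dataset`.
#' @export
prepare_dataset <- function(events, ann, registry, window_seconds = 30,
                            mode = c("indicator", "fraction"), origin = NULL) {
  seg <- segment_events(events, window_seconds, origin)
  X <- extract_features(events, seg, registry, mode)
  label_windows(seg, X, ann)
}
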
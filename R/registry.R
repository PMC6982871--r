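# Sensor registry: the catalogue of binary sensors installed in the smart
# home. Every sensor has exactly two states (e.g. Open/Close); feature
# extraction and event validation are both driven by this table.

.SENSOR_TYPES <- c("Motion", "Contact", "Pressure")

#' Built-in 30-sensor smart-lab registry
#'
#' The reference deployment: a single-inhabitant smart lab instrumented with
#' 30 binary sensors (4 PIR motion detectors, 24 magnetic contact switches,
#' and 2 pressure mats). Used as the default registry throughout the package
#' and by the synthetic event simulator.
#'
#' @return A `sensor_registry` data frame with columns `sensor_id`, `object`,
#'   `type` and `states` (the two states separated by `/`, active state
#'   first).
#' @examples
#' reg <- ucami_registry()
#' nrow(reg)            # 30
#' registry_states(reg, "C14")
#' @export
ucami_registry <- function() {
  txt <- "sensor_id,object,type,states
SM1,Kitchen area,Motion,Movement/No movement
SM3,Bathroom area,Motion,Movement/No movement
SM4,Bedroom area,Motion,Movement/No movement
SM5,Sofa area,Motion,Movement/No movement
M01,Door,Contact,Open/Close
TV0,TV,Contact,Open/Close
D01,Refrigerator,Contact,Open/Close
D02,Microwave,Contact,Open/Close
D03,Wardrobe,Contact,Open/Close
D04,Cups cupboard,Contact,Open/Close
D05,Dishwasher,Contact,Open/Close
D07,WC,Contact,Open/Close
D08,Closet,Contact,Open/Close
D09,Washing machine,Contact,Open/Close
D10,Pantry,Contact,Open/Close
C01,Medication box,Contact,Open/Close
C02,Fruit platter,Contact,Open/Close
C03,Cutlery,Contact,Open/Close
C04,Pots,Contact,Open/Close
C05,Water bottle,Contact,Open/Close
C07,XBOX Remote,Contact,Present/Not present
C08,Trash,Contact,Open/Close
C09,Tap,Contact,Open/Close
C10,Tank,Contact,Open/Close
C12,Laundry basket,Contact,Present/Not present
C13,Pyjamas drawer,Contact,Open/Close
C14,Bed,Pressure,Pressure/No pressure
C15,Kitchen faucet,Contact,Open/Close
H01,Kettle,Contact,Open/Close
S09,Sofa,Pressure,Pressure/No pressure"
  load_registry(txt)
}

#' Load a sensor registry from CSV
#'
#' @param source Path to a CSV file, or a literal CSV string (detected by the
#'   presence of a newline). Required columns: `sensor_id`, `object`, `type`,
#'   `states`; `states` holds the sensor's two states separated by `/`.
#' @return A validated `sensor_registry` data frame.
#' @seealso [ucami_registry()], [write_registry()]
#' @export
load_registry <- function(source) {
  df <- read_table_source(source)
  required <- c("sensor_id", "object", "type", "states")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("registry format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  df <- df[, required, drop = FALSE]
  as_sensor_registry(df)
}

#' Write a sensor registry to CSV
#'
#' @param registry A `sensor_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "sensor_registry"))
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

as_sensor_registry <- function(df) {
  df$sensor_id <- as.character(df$sensor_id)
  df$type <- as.character(df$type)
  df$states <- as.character(df$states)
  if (nrow(df) > 0) {
    dup <- unique(df$sensor_id[duplicated(df$sensor_id)])
    if (length(dup) > 0) {
      stop("registry format error: duplicate sensor id(s) ", paste(dup, collapse = ", "))
    }
    bad_type <- unique(df$type[!df$type %in% .SENSOR_TYPES])
    if (length(bad_type) > 0) {
      stop("registry format error: unknown sensor type(s) ", paste(bad_type, collapse = ", "))
    }
    parts <- strsplit(df$states, "/", fixed = TRUE)
    if (any(vapply(parts, length, 1L) != 2L)) {
      stop("registry format error: every sensor needs exactly 2 states ('A/B')")
    }
  }
  structure(df, class = c("sensor_registry", "data.frame"))
}

#' Look up the state pair of a sensor
#'
#' @param registry A `sensor_registry`.
#' @param sensor_id Sensor identifier.
#' @return Character vector of the sensor's two states (active state first).
#' @export
registry_states <- function(registry, sensor_id) {
  i <- match(sensor_id, registry$sensor_id)
  if (is.na(i)) stop("unknown sensor id: ", sensor_id)
  strsplit(registry$states[i], "/", fixed = TRUE)[[1]]
}

# Read a delimited table from a path or a literal string, auto-detecting
# tab vs comma on the first line.
read_table_source <- function(source, header = TRUE) {
  is_literal <- length(source) == 1 && grepl("\n", source)
  first <- if (is_literal) strsplit(source, "\n", fixed = TRUE)[[1]][1] else readLines(source, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  if (is_literal) {
    utils::read.table(text = source, sep = sep, header = header,
                      stringsAsFactors = FALSE, strip.white = TRUE,
                      fileEncoding = "UTF-8")
  } else {
    utils::read.table(source, sep = sep, header = header,
                      stringsAsFactors = FALSE, strip.white = TRUE,
                      fileEncoding = "UTF-8")
  }
}
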
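# Temporal normalization and unit conversion shared by all extractors.
# All source timestamps are UTC ISO-8601 at second resolution; the analysis
# time zone is Europe/Berlin (CET/CEST), applied one-way UTC -> local so
# ambiguous local times cannot arise.

PDMS_TZ <- "Europe/Berlin"

pdms_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "pdms_error", "error")))
}

#' Parse UTC ISO-8601 timestamps
#'
#' Accepts `"YYYY-MM-DDTHH:MM:SSZ"` (or an explicit `+00:00` offset) strings,
#' or `POSIXct`. `NA` values pass through as `NA`.
#'
#' @param x Character vector of UTC ISO-8601 timestamps, or `POSIXct`.
#' @return `POSIXct` in UTC.
#' @export
parse_utc <- function(x) {
  if (inherits(x, "POSIXt")) {
    x <- as.POSIXct(x)
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.logical(x) && all(is.na(x))) x <- as.character(x)
  if (!is.character(x)) {
    pdms_error("pdms_format_error", "timestamps must be character or POSIXct")
  }
  y <- sub("Z$", "+0000", x)
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", y)
  out <- as.POSIXct(y, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    pdms_error("pdms_format_error",
               sprintf("unparseable UTC timestamp: %s", x[which(bad)[1L]]))
  }
  out
}

#' Render a timestamp as UTC ISO-8601 (`Z` suffix)
#'
#' @param t `POSIXct` vector.
#' @return Character vector, `NA` preserved.
#' @export
format_utc <- function(t) {
  out <- format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out[is.na(t)] <- NA_character_
  out
}

#' Convert UTC timestamps to local CET/CEST representation
#'
#' Applies the Europe/Berlin offset (including daylight-saving transitions via
#' the system tz database) without changing the underlying instant. Output is
#' ISO-8601 with an explicit `+01:00` or `+02:00` offset, so the local
#' representation can always be converted back to the exact instant.
#'
#' @param ts UTC timestamps (character ISO-8601 or `POSIXct`).
#' @return Character vector of local ISO-8601 timestamps with offset.
#' @export
to_local <- function(ts) {
  t <- parse_utc(ts)
  out <- format(t, "%Y-%m-%dT%H:%M:%S%z", tz = PDMS_TZ)
  out <- sub("([+-][0-9]{2})([0-9]{2})$", "\\1:\\2", out)
  out[is.na(t)] <- NA_character_
  out
}

#' Parse a local ISO-8601 timestamp (with offset) back to its UTC instant
#'
#' @param x Character vector, e.g. `"2024-01-15T11:00:00+01:00"`.
#' @return `POSIXct` in UTC.
#' @export
parse_local <- function(x) {
  parse_utc(x)
}

# ---- unit registry -----------------------------------------------------------

#' Load the unit registry
#'
#' The registry is a flat curated table (packaged as editable CSV) mapping a
#' unit symbol to its dimension (mass, volume, activity, time) and the factor
#' to that dimension's base unit (mg, mL, U, h). `U` and `IU` are treated as
#' synonymous activity units.
#'
#' @param path Optional path to an alternative registry CSV with columns
#'   `unit, dimension, to_base`.
#' @return Data frame with columns `unit`, `dimension`, `to_base`.
#' @export
unit_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "units.csv", package = "pdmsetl")
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stopifnot(all(c("unit", "dimension", "to_base") %in% names(reg)))
  reg
}

.unit_cache <- new.env(parent = emptyenv())

default_unit_registry <- function() {
  if (is.null(.unit_cache$reg)) .unit_cache$reg <- unit_registry()
  .unit_cache$reg
}

#' Convert a value between units of the same dimension
#'
#' @param value Numeric vector.
#' @param from_unit,to_unit Unit symbols registered in the unit registry.
#' @param registry Unit registry data frame (defaults to the packaged one).
#' @return Converted numeric vector.
#' @export
#' @examples
#' convert_unit(500, "ug", "mg")  # 0.5
convert_unit <- function(value, from_unit, to_unit,
                         registry = default_unit_registry()) {
  i <- match(from_unit, registry$unit)
  j <- match(to_unit, registry$unit)
  if (is.na(i)) pdms_error("pdms_unit_error", sprintf("unknown unit: %s", from_unit))
  if (is.na(j)) pdms_error("pdms_unit_error", sprintf("unknown unit: %s", to_unit))
  if (registry$dimension[i] != registry$dimension[j]) {
    pdms_error("pdms_dimension_error",
               sprintf("cannot convert %s (%s) to %s (%s)",
                       from_unit, registry$dimension[i],
                       to_unit, registry$dimension[j]))
  }
  value * registry$to_base[i] / registry$to_base[j]
}
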
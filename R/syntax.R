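# Micro-syntaxes of the transfer format: pipe-separated lists, yes/no cells,
# ISO 8601 timestamps, combined names, substrate class:percent pairs and
# plain decimal numbers. Lenient in, strict out: parsers tolerate minor
# formatting slack, writers always emit the canonical form.

PIPE_SEP <- " | "

#' Split and join pipe-separated list cells
#'
#' Multi-valued cells in both tables hold their values separated by a
#' vertical bar, canonically written with a surrounding space on each side
#' (`" | "`). `split_pipe_list()` is total: it tolerates missing spaces,
#' trims each element and drops empties, so a blank cell yields an empty
#' character vector. `join_pipe_list()` emits the canonical separator.
#'
#' @param cell A single character cell (may be `NA` or empty).
#' @param values A character vector.
#' @return `split_pipe_list()`: a character vector of elements;
#'   `join_pipe_list()`: a single string (empty for an empty input).
#' @examples
#' split_pipe_list("a.jpg | b.jpg")
#' split_pipe_list("a.jpg|b.jpg")
#' join_pipe_list(c("a.jpg", "b.jpg"))
#' @export
split_pipe_list <- function(cell) {
  if (length(cell) != 1) stop("`cell` must be a single string", call. = FALSE)
  if (is.na(cell) || !nzchar(trimws(cell))) return(character())
  parts <- trimws(strsplit(cell, "|", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

#' @rdname split_pipe_list
#' @export
join_pipe_list <- function(values) {
  values <- values[!is.na(values) & nzchar(trimws(values))]
  paste(trimws(values), collapse = PIPE_SEP)
}

#' Build a combined morphospecies name
#'
#' The combined name of an OTU is its scientific name followed by its
#' morphospecies qualifier, joined by a single space: `"Brisingidae"` +
#' `"msp1"` gives `"Brisingidae msp1"`. Internal runs of whitespace in
#' either component are collapsed. Both components are required fields of
#' the OTU table, so an empty component is an error.
#'
#' @param scientific_name Taxon name at the lowest rank identified.
#' @param morphospecies Morphospecies qualifier, e.g. `"msp1"` or
#'   `"encrusting msp1"`.
#' @return A single combined-name string.
#' @examples
#' make_combined_name("Brisingidae", "msp1")
#' make_combined_name("Porifera", "branching msp1")
#' @export
make_combined_name <- function(scientific_name, morphospecies) {
  squeeze <- function(x) gsub("\\s+", " ", trimws(x))
  sn <- squeeze(scientific_name)
  ms <- squeeze(morphospecies)
  bad <- is.na(sn) | !nzchar(sn) | is.na(ms) | !nzchar(ms)
  if (any(bad)) {
    stop("both scientific_name and morphospecies are required to form a combined name",
         call. = FALSE)
  }
  paste(sn, ms)
}

#' Parse a yes/no cell
#'
#' The `PhysicalSample` field is a yes/no field. Parsing is
#' case-insensitive and accepts `yes`/`y`/`true` and `no`/`n`/`false`;
#' anything else is a parse error naming the offending field.
#'
#' @param cell A single string.
#' @param field Field name used in the error message.
#' @return `TRUE` or `FALSE` (`NA` for an empty cell).
#' @examples
#' parse_flexible_boolean("Yes")
#' parse_flexible_boolean("no")
#' @export
parse_flexible_boolean <- function(cell, field = "PhysicalSample") {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NA)
  token <- tolower(trimws(cell))
  if (token %in% c("yes", "y", "true")) return(TRUE)
  if (token %in% c("no", "n", "false")) return(FALSE)
  stop(sprintf("field '%s': cannot interpret '%s' as yes/no", field, cell),
       call. = FALSE)
}

format_boolean <- function(x) {
  ifelse(is.na(x), "", ifelse(x, "Yes", "No"))
}

RE_DATE <- "^\\d{4}-\\d{2}-\\d{2}$"
RE_DATETIME <- "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z?$"

#' Parse an ISO 8601 date or date-time cell
#'
#' Date fields use ISO 8601 (e.g. `1973-02-28T15:25:00`). Date-only values
#' are legal (older catalogues rarely record time of identification) and
#' their precision is preserved so that a catalogue round-trips losslessly:
#' a date-only cell parses to a `Date`, a full timestamp to a UTC
#' `POSIXct`. Any non-ISO form is rejected.
#'
#' @param cell A single string.
#' @param field Field name used in the error message.
#' @return A `Date`, a `POSIXct`, or `NA` for an empty cell.
#' @examples
#' parse_timestamp("1973-02-28T15:25:00")
#' parse_timestamp("2017-12-04")
#' @export
parse_timestamp <- function(cell, field = "dateIdentified") {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NA)
  cell <- trimws(cell)
  if (grepl(RE_DATE, cell)) {
    out <- as.Date(cell, format = "%Y-%m-%d")
    if (is.na(out)) stop(sprintf("field '%s': impossible date '%s'", field, cell), call. = FALSE)
    return(out)
  }
  if (grepl(RE_DATETIME, cell)) {
    out <- as.POSIXct(sub("Z$", "", cell), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    if (is.na(out)) stop(sprintf("field '%s': impossible date-time '%s'", field, cell), call. = FALSE)
    return(out)
  }
  stop(sprintf(
    "field '%s': '%s' is not ISO 8601 (expected YYYY-MM-DD or YYYY-MM-DDThh:mm:ss)",
    field, cell
  ), call. = FALSE)
}

#' @rdname parse_timestamp
#' @param x A value returned by `parse_timestamp()`.
#' @export
format_timestamp <- function(x) {
  if (length(x) == 1 && is.na(x)[1]) return("")
  if (inherits(x, "POSIXct")) return(format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  if (inherits(x, "Date")) return(format(x, "%Y-%m-%d"))
  stop("not a parsed timestamp", call. = FALSE)
}

# Validate a timestamp cell and return it in canonical string form (cells are
# carried as validated strings so date vs date-time precision survives I/O).
canonical_timestamp_cell <- function(cell, field) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NA_character_)
  format_timestamp(parse_timestamp(cell, field = field))
}

# Plain decimal numbers: point decimal separator, optional sign; thousands
# separators and locale forms rejected.
parse_decimal_cell <- function(cell, field) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NA_real_)
  cell <- trimws(cell)
  if (!grepl("^[+-]?(\\d+\\.?\\d*|\\.\\d+)$", cell)) {
    stop(sprintf("field '%s': '%s' is not a plain decimal number", field, cell),
         call. = FALSE)
  }
  as.numeric(cell)
}

format_decimal <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1)))
}

parse_integer_cell <- function(cell, field) {
  if (is.na(cell) || !nzchar(trimws(cell))) return(NA_integer_)
  cell <- trimws(cell)
  if (!grepl("^[+-]?\\d+$", cell)) {
    stop(sprintf("field '%s': '%s' is not an integer", field, cell), call. = FALSE)
  }
  as.integer(cell)
}

#' Parse and format substrate composition cells
#'
#' The `SubstrateType` cell records the substrate classes visible in the
#' image and, optionally, the percentage cover of each, encoded as
#' `"class: percent"` pairs separated by the standard vertical-bar list
#' separator, e.g. `"bedrock: 70 | pebble: 30"`. A bare class with no
#' percentage is legal.
#'
#' @param cell A single string.
#' @param substrate A tibble with columns `class` and `percent`.
#' @return `parse_substrate()`: a tibble with character `class` and numeric
#'   `percent` (NA where no percentage was given); `format_substrate()`: the
#'   canonical cell string.
#' @examples
#' parse_substrate("bedrock: 70 | pebble: 30")
#' format_substrate(tibble::tibble(class = "sand", percent = NA_real_))
#' @export
parse_substrate <- function(cell) {
  parts <- split_pipe_list(if (length(cell)) cell else NA_character_)
  if (!length(parts)) {
    return(tibble::tibble(class = character(), percent = numeric()))
  }
  cls <- character(length(parts))
  pct <- rep(NA_real_, length(parts))
  for (i in seq_along(parts)) {
    if (grepl(":", parts[i], fixed = TRUE)) {
      kv <- strsplit(parts[i], ":", fixed = TRUE)[[1]]
      if (length(kv) != 2) {
        stop(sprintf("field 'SubstrateType': cannot parse '%s'", parts[i]), call. = FALSE)
      }
      cls[i] <- trimws(kv[1])
      pct[i] <- parse_decimal_cell(trimws(kv[2]), "SubstrateType")
    } else {
      cls[i] <- trimws(parts[i])
    }
  }
  tibble::tibble(class = cls, percent = pct)
}

#' @rdname parse_substrate
#' @export
format_substrate <- function(substrate) {
  if (is.null(substrate) || !nrow(substrate)) return("")
  pieces <- ifelse(
    is.na(substrate$percent),
    substrate$class,
    paste0(substrate$class, ": ", format_decimal(substrate$percent))
  )
  join_pipe_list(pieces)
}
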
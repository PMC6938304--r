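# The catalogue container and the CSV carrier of the transfer format.
#
# A catalogue is a related pair of tables: one OTU table row per operational
# taxonomic unit, one image table row per occurrence/image entry, related
# through the OTU field. Multi-valued cells are held as list-columns; all
# other values are typed per the field dictionary. Two modes exist:
# "transfer" (stage-1 exchange files, where GUIDs and autopopulated fields
# may be absent) and "canonical" (curated database, everything populated).

#' Construct a catalogue
#'
#' Bundles an OTU table and an image table (as returned by the readers or
#' builders in this package) with the directory of referenced image files
#' and provenance metadata. Structural invariants of the container itself
#' are enforced here (column presence and types); conformance to the
#' standard is checked separately by [validate_catalogue()].
#'
#' @param otu Tibble with the OTU-table columns (see [otu_field_dictionary()]).
#' @param images Tibble with the image-table columns (see
#'   [image_field_dictionary()]).
#' @param image_dir Directory holding the referenced image files, or `NA`.
#' @param source_label Label identifying the submitting group or source
#'   catalogue; used for merge provenance.
#' @param mode `"transfer"` or `"canonical"`.
#' @param extra Optional list with `otu` and/or `image` tibbles holding
#'   unrecognised columns preserved from a read file.
#' @return An object of class `smartar_catalogue`.
#' @export
new_catalogue <- function(otu = empty_otu_table(), images = empty_image_table(),
                          image_dir = NA_character_, source_label = "unlabelled",
                          mode = c("transfer", "canonical"), extra = list()) {
  mode <- match.arg(mode)
  otu_defs <- otu_field_defs()
  img_defs <- image_field_defs()
  missing_otu <- setdiff(otu_defs$name, names(otu))
  missing_img <- setdiff(img_defs$name, names(images))
  if (length(missing_otu)) {
    stop("OTU table is missing columns: ", paste(missing_otu, collapse = ", "), call. = FALSE)
  }
  if (length(missing_img)) {
    stop("image table is missing columns: ", paste(missing_img, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      otu = otu[, otu_defs$name],
      images = images[, img_defs$name],
      image_dir = image_dir,
      source_label = source_label,
      mode = mode,
      extra = extra
    ),
    class = "smartar_catalogue"
  )
}

#' @rdname new_catalogue
#' @param x Object to test or print.
#' @export
is_catalogue <- function(x) inherits(x, "smartar_catalogue")

#' @rdname new_catalogue
#' @param ... Ignored.
#' @export
print.smartar_catalogue <- function(x, ...) {
  cat(sprintf(
    "<catalogue [%s]> %d OTUs, %d image records (source: %s)\n",
    x$mode, nrow(x$otu), nrow(x$images), x$source_label
  ))
  if (!is.na(x$image_dir)) cat("  image dir:", x$image_dir, "\n")
  invisible(x)
}

#' Empty typed catalogue tables
#'
#' Zero-row tibbles with the full typed column set of each table; useful as
#' builders and as the column reference for programmatic construction.
#'
#' @return A zero-row tibble.
#' @export
empty_otu_table <- function() {
  tibble::tibble(
    number = character(), otu = character(), scientific_name = character(),
    scientific_name_id = character(), scientific_name_authorship = character(),
    taxon_rank = character(), morphospecies = character(),
    combined_name_id = character(), previous_name = list(),
    identification_features = character(), iconic_image = list()
  )
}

#' @rdname empty_otu_table
#' @export
empty_image_table <- function() {
  tibble::tibble(
    number = character(), otu = character(), insitu_image_names = list(),
    exsitu_image_names = list(), physical_sample = logical(),
    image_credits = character(), identified_by = character(),
    date_identified = character(), identification_remarks = character(),
    identification_verification_status = integer(), type_status = character(),
    raw_image = character(), locality = character(), location_id = character(),
    location_remarks = character(), decimal_latitude = numeric(),
    decimal_longitude = numeric(), minimum_depth_m = numeric(),
    maximum_depth_m = numeric(), institution_id = character(),
    collection_id = character(), bibliographic_citation = character(),
    modified = character(), license = character(), rights_holder = character(),
    access_rights = character(), previous_identifications = list(),
    catalog_number = character(), associated_sequences = character(),
    habitat = character(), substrate_type = list(), size_cm = numeric(),
    substrate_method = character(), project_name = character(),
    external_link = character()
  )
}

cell_error <- function(table, row, field, message) {
  stop(sprintf("[%s table, row %d, field '%s'] %s", table, row, field, message),
       call. = FALSE)
}

# Parse one raw character column into its typed form, converting parser
# errors into errors that carry (table, row, field).
parse_column <- function(raw, def, table) {
  n <- length(raw)
  wrap <- function(i, expr) {
    tryCatch(expr, error = function(e) cell_error(table, i, def$header, conditionMessage(e)))
  }
  switch(def$type,
    character = blank_to_na(raw),
    list = lapply(raw, function(cell) split_pipe_list(cell %||% NA_character_)),
    logical = vapply(seq_len(n), function(i) {
      wrap(i, parse_flexible_boolean(raw[i], field = def$header))
    }, logical(1)),
    integer = vapply(seq_len(n), function(i) {
      wrap(i, parse_integer_cell(raw[i], field = def$header))
    }, integer(1)),
    numeric = vapply(seq_len(n), function(i) {
      wrap(i, parse_decimal_cell(raw[i], field = def$header))
    }, numeric(1)),
    timestamp = vapply(seq_len(n), function(i) {
      wrap(i, canonical_timestamp_cell(raw[i], field = def$header))
    }, character(1)),
    substrate = lapply(seq_len(n), function(i) wrap(i, parse_substrate(raw[i]))),
    stop("unknown field type: ", def$type)
  )
}

format_column <- function(values, def) {
  switch(def$type,
    character = na_to_blank(values),
    timestamp = na_to_blank(values),
    list = vapply(values, join_pipe_list, character(1)),
    logical = format_boolean(values),
    integer = ifelse(is.na(values), "", as.character(values)),
    numeric = format_decimal(values),
    substrate = vapply(values, format_substrate, character(1)),
    stop("unknown field type: ", def$type)
  )
}

read_table_file <- function(path, table, mode) {
  defs <- field_defs(table)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE,
                         name_repair = "minimal")
  headers <- names(raw)
  tolerated <- if (mode == "transfer") {
    defs$status %in% transfer_optional_statuses | defs$status == "optional"
  } else {
    rep(FALSE, nrow(defs))
  }
  missing <- setdiff(defs$header[!tolerated], headers)
  if (length(missing)) {
    stop(sprintf(
      "%s table '%s' is missing required column(s): %s",
      table, path, paste(sprintf("'%s'", missing), collapse = ", ")
    ), call. = FALSE)
  }
  n <- nrow(raw)
  cols <- vector("list", nrow(defs))
  names(cols) <- defs$name
  for (k in seq_len(nrow(defs))) {
    def <- defs[k, ]
    raw_col <- if (def$header %in% headers) raw[[def$header]] else rep(NA_character_, n)
    cols[[def$name]] <- parse_column(raw_col, def, table)
  }
  parsed <- tibble::as_tibble(cols)
  unknown <- setdiff(headers, defs$header)
  extra <- if (length(unknown)) raw[, unknown, drop = FALSE] else NULL
  list(table = parsed, extra = extra, unknown = unknown)
}

#' Read a catalogue from its two-table CSV transfer files
#'
#' Parses the OTU table and the image table through the format's
#' micro-syntaxes (pipe-separated lists, yes/no cells, ISO 8601 timestamps,
#' substrate class:percent pairs, plain decimal numbers). Column-name
#' matching is exact and case-sensitive against the published headers. In
#' `"transfer"` mode, GUID, autopopulated and optional columns may be
#' absent (stage-1 exchange files need not populate them); in
#' `"canonical"` mode every column must be present. Unknown columns are
#' preserved in the catalogue's `extra` slot and reported.
#'
#' @param otu_table_path,image_table_path Paths to the two CSV files.
#' @param image_dir Directory of referenced image files (optional; needed
#'   only for file-existence validation and guide building).
#' @param mode `"transfer"` or `"canonical"`.
#' @param source_label Provenance label for the catalogue; defaults to the
#'   OTU table's directory name.
#' @param quiet Suppress the unknown-column report.
#' @return A [new_catalogue()] object.
#' @export
read_catalogue <- function(otu_table_path, image_table_path, image_dir = NA_character_,
                           mode = c("transfer", "canonical"),
                           source_label = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  for (p in c(otu_table_path, image_table_path)) {
    if (!file.exists(p)) stop("file does not exist: ", p, call. = FALSE)
  }
  otu_read <- read_table_file(otu_table_path, "otu", mode)
  img_read <- read_table_file(image_table_path, "image", mode)
  unknown <- c(
    if (length(otu_read$unknown)) paste0("otu: ", otu_read$unknown),
    if (length(img_read$unknown)) paste0("image: ", img_read$unknown)
  )
  if (length(unknown) && !quiet) {
    message("preserving unknown column(s): ", paste(unknown, collapse = ", "))
  }
  extra <- list()
  if (!is.null(otu_read$extra)) extra$otu <- otu_read$extra
  if (!is.null(img_read$extra)) extra$image <- img_read$extra
  new_catalogue(
    otu = otu_read$table, images = img_read$table, image_dir = image_dir,
    source_label = source_label %||% basename(dirname(normalizePath(otu_table_path))),
    mode = mode, extra = extra
  )
}

#' Write a catalogue to its two-table CSV transfer files
#'
#' Serialises a catalogue back to the two CSV files of the transfer format.
#' Headers are emitted exactly as published (including the `dcterms:`
#' prefixes and the `Link to external database` header), in table order;
#' multi-valued cells use the canonical `" | "` separator. Reading the
#' written files back reproduces the catalogue field-for-field.
#'
#' @param cat A catalogue.
#' @param out_dir Output directory (created if needed).
#' @param otu_file,image_file File names within `out_dir`.
#' @return Named character vector with elements `otu_table` and
#'   `image_table` (the written paths), invisibly.
#' @export
write_catalogue <- function(cat, out_dir, otu_file = "otu_table.csv",
                            image_file = "image_table.csv") {
  stopifnot(is_catalogue(cat))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    otu_table = file.path(out_dir, otu_file),
    image_table = file.path(out_dir, image_file)
  )
  for (table in c("otu", "image")) {
    defs <- field_defs(table)
    data <- if (table == "otu") cat$otu else cat$images
    out <- lapply(seq_len(nrow(defs)), function(k) format_column(data[[defs$name[k]]], defs[k, ]))
    names(out) <- defs$header
    out <- tibble::as_tibble(out, .name_repair = "minimal")
    extra <- cat$extra[[if (table == "otu") "otu" else "image"]]
    if (!is.null(extra) && nrow(extra) == nrow(out)) {
      out <- dplyr::bind_cols(out, extra, .name_repair = "minimal")
    }
    readr::write_csv(out, paths[[if (table == "otu") "otu_table" else "image_table"]],
                     na = "", progress = FALSE)
  }
  invisible(paths)
}
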
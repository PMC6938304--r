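# Conformance validation: field-, record- and catalogue-level checks against
# the standard, producing machine-readable issues. Validation is pure — the
# same catalogue and stores always yield the same issue list, in a stable
# order (table, record, field, rule).
#
# Rule codes (closed, documented set):
#   REQ_FIELD          required field empty (per mode)
#   VSTATUS_RANGE      identificationVerificationStatus outside {1,2,3}
#   DEPTH_ORDER        minimumDepthInMeters > maximumDepthInMeters
#   DEPTH_POSITIVE     non-positive depth (positive metres required)
#   COORD_RANGE        latitude outside [-90,90] or longitude outside [-180,180]
#   SIZE_POSITIVE      non-positive Size (cm)
#   SUBSTRATE_METHOD   SubstrateMethod outside {Folk, Wentworth, EUNIS, Other}
#   LSID_FORMAT        scientificNameID not a well-formed LSID
#   STATUS3_NOSAMPLE   status 3 claimed without a physical sample
#   XREF_OTU           image row references an OTU absent from the OTU table
#   OTU_EMPTY          OTU with no image rows (warning)
#   ICONIC_MISSING     IconicImage name not among that OTU's image files
#   EXSITU_ALONE       ex-situ images present without any in-situ image
#   TAXON_MISS         LSID's AphiaID absent from the taxon store
#   NAME_MISMATCH      stored taxonomy fields disagree with the taxon store
#   UNACCEPTED_NAME    LSID resolves to an unaccepted name (warning)
#   REGION_MISS        locationID absent from the gazetteer store
#   LOCALITY_MISMATCH  locality string differs from the gazetteer entry
#   FILE_MISSING       referenced image file absent from image_dir
#   DUP_NAME           same CombinedNameID on distinct OTUs (warning)
#   GUID_DUP           duplicate Number within a table (canonical mode)

issue_row <- function(severity, rule_code, table, record_ref, field, message) {
  tibble::tibble(
    severity = severity, rule_code = rule_code, table = table,
    record_ref = record_ref %||% NA_character_, field = field %||% NA_character_,
    message = message
  )
}

empty_issues <- function() {
  tibble::tibble(
    severity = character(), rule_code = character(), table = character(),
    record_ref = character(), field = character(), message = character()
  )
}

record_ref_of <- function(data, i, table) {
  if (!is.na(data$number[i]) && nzchar(data$number[i])) {
    data$number[i]
  } else if (table == "otu") {
    data$otu[i] %||% sprintf("row %d", i)
  } else {
    sprintf("row %d", i)
  }
}

# Fields whose emptiness is checked per mode: required always; autopopulate
# and GUID fields only in canonical mode.
required_in_mode <- function(defs, mode) {
  if (mode == "canonical") {
    defs[defs$status %in% c("required", "guid", "autopopulate"), ]
  } else {
    defs[defs$status == "required", ]
  }
}

field_is_empty <- function(data, name, i) {
  v <- data[[name]][[i]]
  if (is.data.frame(v)) return(nrow(v) == 0)
  if (is.list(v)) v <- unlist(v)
  length(v) == 0 || all(is.na(v)) || all(!nzchar(trimws(as.character(v))))
}

validate_otu_row <- function(otu, i, mode) {
  issues <- list()
  ref <- record_ref_of(otu, i, "otu")
  req <- required_in_mode(otu_field_defs(), mode)
  for (k in seq_len(nrow(req))) {
    if (field_is_empty(otu, req$name[k], i)) {
      issues[[length(issues) + 1]] <- issue_row(
        "error", "REQ_FIELD", "otu", ref, req$header[k],
        sprintf("required field '%s' is empty", req$header[k])
      )
    }
  }
  lsid <- otu$scientific_name_id[i]
  if (!is.na(lsid) && nzchar(lsid)) {
    ok <- tryCatch({parse_lsid(lsid); TRUE}, error = function(e) FALSE)
    if (!ok) {
      issues[[length(issues) + 1]] <- issue_row(
        "error", "LSID_FORMAT", "otu", ref, "scientificNameID",
        sprintf("'%s' is not a well-formed LSID", lsid)
      )
    }
  }
  issues
}

validate_image_row <- function(images, i, mode) {
  issues <- list()
  ref <- record_ref_of(images, i, "image")
  add <- function(severity, rule, field, msg) {
    issues[[length(issues) + 1]] <<- issue_row(severity, rule, "image", ref, field, msg)
  }
  req <- required_in_mode(image_field_defs(), mode)
  for (k in seq_len(nrow(req))) {
    if (field_is_empty(images, req$name[k], i)) {
      add("error", "REQ_FIELD", req$header[k],
          sprintf("required field '%s' is empty", req$header[k]))
    }
  }
  status <- images$identification_verification_status[i]
  if (!is.na(status) && !(status %in% 1:3)) {
    add("error", "VSTATUS_RANGE", "identificationVerificationStatus",
        sprintf("verification status %d outside 1-3", status))
  }
  if (!is.na(status) && status == 3L && identical(images$physical_sample[i], FALSE)) {
    add("error", "STATUS3_NOSAMPLE", "identificationVerificationStatus",
        "status 3 requires the specific physical specimen (PhysicalSample = Yes)")
  }
  dmin <- images$minimum_depth_m[i]
  dmax <- images$maximum_depth_m[i]
  for (d in list(c("minimumDepthInMeters", dmin), c("maximumDepthInMeters", dmax))) {
    v <- as.numeric(d[2])
    if (!is.na(v) && v <= 0) {
      add("error", "DEPTH_POSITIVE", d[1], sprintf("depth must be positive, got %s", d[2]))
    }
  }
  if (!is.na(dmin) && !is.na(dmax) && dmin > 0 && dmax > 0 && dmin > dmax) {
    add("error", "DEPTH_ORDER", "minimumDepthInMeters",
        sprintf("minimum depth %s m exceeds maximum depth %s m", dmin, dmax))
  }
  lat <- images$decimal_latitude[i]
  lon <- images$decimal_longitude[i]
  if (!is.na(lat) && (lat < -90 || lat > 90)) {
    add("error", "COORD_RANGE", "decimalLatitude",
        sprintf("latitude %s outside [-90, 90]", lat))
  }
  if (!is.na(lon) && (lon < -180 || lon > 180)) {
    add("error", "COORD_RANGE", "decimalLongitude",
        sprintf("longitude %s outside [-180, 180]", lon))
  }
  size <- images$size_cm[i]
  if (!is.na(size) && size <= 0) {
    add("error", "SIZE_POSITIVE", "Size", sprintf("size must be positive cm, got %s", size))
  }
  method <- images$substrate_method[i]
  if (!is.na(method) && nzchar(method) && !(method %in% substrate_methods)) {
    add("error", "SUBSTRATE_METHOD", "SubstrateMethod",
        sprintf("'%s' is not one of %s", method, paste(substrate_methods, collapse = ", ")))
  }
  if (length(images$exsitu_image_names[[i]]) > 0 && length(images$insitu_image_names[[i]]) == 0) {
    add("error", "EXSITU_ALONE", "ExsituImageName",
        "ex-situ images may only accompany an in-situ image of the same individual")
  }
  issues
}

#' Validate a single catalogue record
#'
#' Runs the record-level rules on one row of either table: required-field
#' presence (per mode), verification-status range, depth positivity and
#' ordering, coordinate ranges, size positivity, substrate-method
#' vocabulary, LSID well-formedness, the status-3-needs-a-specimen rule and
#' the ex-situ-only-with-in-situ rule.
#'
#' @param rec A one-row tibble from a catalogue's `otu` or `images` table.
#' @param mode `"transfer"` or `"canonical"`; in transfer mode GUID and
#'   autopopulated fields may be empty.
#' @return A tibble of issues (`severity`, `rule_code`, `table`,
#'   `record_ref`, `field`, `message`); zero rows when the record conforms.
#' @export
validate_record <- function(rec, mode = c("transfer", "canonical")) {
  mode <- match.arg(mode)
  stopifnot(nrow(rec) == 1)
  issues <- if ("insitu_image_names" %in% names(rec)) {
    validate_image_row(rec, 1, mode)
  } else {
    validate_otu_row(rec, 1, mode)
  }
  finalize_issues(issues)
}

finalize_issues <- function(issues) {
  if (!length(issues)) return(empty_issues())
  out <- dplyr::bind_rows(issues)
  out[order(out$table, out$record_ref, out$field, out$rule_code, method = "radix"), ]
}

#' Validate a whole catalogue
#'
#' Record-level rules on every row of both tables plus the cross-record and
#' cross-table rules of the standard: referential integrity of the `OTU`
#' link, OTUs without images (warning), iconic images that are not among
#' the OTU's own image files, ex-situ-only records, a taxonomy dry-run
#' against the taxon store (misses, stale names, unaccepted names),
#' gazetteer resolution and locality cross-check, duplicate combined names
#' (warning), duplicate GUIDs in canonical mode, and — when `check_files`
#' — existence of every referenced image file in the catalogue's image
#' directory.
#'
#' @param cat A catalogue.
#' @param taxa Optional [taxon_store()]; taxonomy checks are skipped when
#'   absent.
#' @param regions Optional [region_store()]; gazetteer checks are skipped
#'   when absent.
#' @param check_files Check referenced image files exist in `image_dir`.
#' @return A tibble of issues in stable order.
#' @export
validate_catalogue <- function(cat, taxa = NULL, regions = NULL, check_files = FALSE) {
  stopifnot(is_catalogue(cat))
  issues <- list()
  add <- function(x) issues[[length(issues) + 1]] <<- x
  otu <- cat$otu
  images <- cat$images
  for (i in seq_len(nrow(otu))) {
    for (x in validate_otu_row(otu, i, cat$mode)) add(x)
  }
  for (i in seq_len(nrow(images))) {
    for (x in validate_image_row(images, i, cat$mode)) add(x)
  }

  # referential integrity and OTU image coverage
  for (i in seq_len(nrow(images))) {
    if (!is.na(images$otu[i]) && !(images$otu[i] %in% otu$otu)) {
      add(issue_row("error", "XREF_OTU", "image", record_ref_of(images, i, "image"), "OTU",
                    sprintf("image references OTU '%s' absent from the OTU table", images$otu[i])))
    }
  }
  for (i in seq_len(nrow(otu))) {
    if (!is.na(otu$otu[i]) && !(otu$otu[i] %in% images$otu)) {
      add(issue_row("warning", "OTU_EMPTY", "otu", record_ref_of(otu, i, "otu"), "OTU",
                    sprintf("OTU '%s' has no image records", otu$otu[i])))
    }
  }

  # iconic images must be among the OTU's own in-situ/ex-situ files
  for (i in seq_len(nrow(otu))) {
    iconic <- otu$iconic_image[[i]]
    if (!length(iconic)) next
    rows <- which(images$otu == otu$otu[i])
    files <- unique(c(
      unlist(images$insitu_image_names[rows]), unlist(images$exsitu_image_names[rows])
    ))
    missing <- setdiff(iconic, files)
    for (f in missing) {
      add(issue_row("error", "ICONIC_MISSING", "otu", record_ref_of(otu, i, "otu"), "IconicImage",
                    sprintf("iconic image '%s' is not among the image files of OTU '%s'",
                            f, otu$otu[i])))
    }
  }

  # taxonomy dry-run
  if (!is.null(taxa)) {
    for (i in seq_len(nrow(otu))) {
      lsid <- otu$scientific_name_id[i]
      if (is.na(lsid) || !nzchar(lsid)) next
      aphia <- tryCatch(parse_lsid(lsid), error = function(e) NA_integer_)
      if (is.na(aphia)) next  # already reported as LSID_FORMAT
      entry <- taxon_lookup(taxa, aphia)
      ref <- record_ref_of(otu, i, "otu")
      if (is.null(entry)) {
        add(issue_row("error", "TAXON_MISS", "otu", ref, "scientificNameID",
                      sprintf("AphiaID %d not found in the taxon store", aphia)))
        next
      }
      pairs <- list(
        c("scientific_name", "scientificName", entry$scientific_name),
        c("scientific_name_authorship", "scientificNameAuthorship", entry$authorship),
        c("taxon_rank", "taxonRank", entry$rank)
      )
      for (p in pairs) {
        val <- otu[[p[1]]][i]
        if (!is.na(val) && nzchar(val) && !identical(val, p[3])) {
          add(issue_row("error", "NAME_MISMATCH", "otu", ref, p[2],
                        sprintf("'%s' disagrees with the taxon store value '%s'", val, p[3])))
        }
      }
      cn <- otu$combined_name_id[i]
      if (!is.na(cn) && nzchar(cn) && !is.na(otu$morphospecies[i]) &&
          nzchar(otu$morphospecies[i])) {
        expect <- make_combined_name(entry$scientific_name, otu$morphospecies[i])
        if (!identical(cn, expect)) {
          add(issue_row("error", "NAME_MISMATCH", "otu", ref, "CombinedNameID",
                        sprintf("'%s' should be '%s'", cn, expect)))
        }
      }
      if (!isTRUE(entry$accepted)) {
        add(issue_row("warning", "UNACCEPTED_NAME", "otu", ref, "scientificNameID",
                      sprintf("'%s' resolves to an unaccepted name", entry$scientific_name)))
      }
    }
  }

  # gazetteer resolution and locality cross-check
  if (!is.null(regions)) {
    for (i in seq_len(nrow(images))) {
      lid <- images$location_id[i]
      if (is.na(lid) || !nzchar(lid)) next
      res <- resolve_region(regions, lid, images$locality[i])
      ref <- record_ref_of(images, i, "image")
      if (!res$found) {
        add(issue_row("error", "REGION_MISS", "image", ref, "locationID",
                      sprintf("locationID '%s' not found in the gazetteer store", lid)))
      } else if (identical(res$locality_match, FALSE)) {
        add(issue_row("error", "LOCALITY_MISMATCH", "image", ref, "locality",
                      sprintf("locality '%s' differs from gazetteer locality '%s'",
                              images$locality[i], res$entry$locality)))
      }
    }
  }

  # duplicate combined names across distinct OTUs (warning)
  cn <- otu$combined_name_id
  dup_names <- unique(cn[!is.na(cn) & nzchar(cn) & duplicated(cn)])
  for (d in dup_names) {
    rows <- which(cn == d)
    for (i in rows) {
      add(issue_row("warning", "DUP_NAME", "otu", record_ref_of(otu, i, "otu"), "CombinedNameID",
                    sprintf("CombinedNameID '%s' appears on %d OTUs", d, length(rows))))
    }
  }

  # canonical mode: GUID uniqueness
  if (cat$mode == "canonical") {
    for (tab in list(list(otu, "otu"), list(images, "image"))) {
      nums <- tab[[1]]$number
      dups <- unique(nums[!is.na(nums) & duplicated(nums)])
      for (d in dups) {
        add(issue_row("error", "GUID_DUP", tab[[2]], d, "Number",
                      sprintf("GUID '%s' is not unique within the %s table", d, tab[[2]])))
      }
    }
  }

  # file existence
  if (check_files) {
    if (is.na(cat$image_dir)) {
      add(issue_row("error", "FILE_MISSING", "image", NA_character_, NA_character_,
                    "check_files requested but the catalogue has no image_dir"))
    } else {
      for (i in seq_len(nrow(images))) {
        files <- c(images$insitu_image_names[[i]], images$exsitu_image_names[[i]])
        for (f in files) {
          if (!file.exists(file.path(cat$image_dir, f))) {
            add(issue_row("error", "FILE_MISSING", "image",
                          record_ref_of(images, i, "image"), "InsituImageName",
                          sprintf("referenced image file '%s' not found in image_dir", f)))
          }
        }
      }
    }
  }

  finalize_issues(issues)
}

#' Summarise a validation issue list
#'
#' Cross-tabulates issues by rule code and severity. The per-rule counts
#' partition the issue list: their sum equals its length.
#'
#' @param issues An issue tibble from [validate_catalogue()] or
#'   [validate_record()].
#' @return Tibble with columns `rule_code`, `severity`, `n`, sorted by
#'   descending count.
#' @export
summarize_issues <- function(issues) {
  if (!nrow(issues)) {
    return(tibble::tibble(rule_code = character(), severity = character(), n = integer()))
  }
  out <- dplyr::count(issues, .data$rule_code, .data$severity, name = "n")
  dplyr::arrange(out, dplyr::desc(.data$n), .data$rule_code)
}

#' Exit code of a validation run
#'
#' Command-line contract: 0 for a clean catalogue, 1 when only warnings
#' were found, 2 when any error was found.
#'
#' @param issues An issue tibble.
#' @return Integer 0, 1 or 2.
#' @export
issues_exit_code <- function(issues) {
  if (!nrow(issues)) return(0L)
  if (any(issues$severity == "error")) 2L else 1L
}
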
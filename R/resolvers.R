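# Offline reference stores: a taxonomy store mirroring the WoRMS contract
# (AphiaID, LSID, name, authorship, rank, parent chain, accepted flag) and a
# gazetteer store mirroring Marine Regions (MRGID-style locationID, locality
# name, placetype). Lookups are total over the fixture's keys; misses are
# reported, never fabricated. A live-service adapter could sit behind the
# same contract, but the core and all tests are network-free.

LSID_PREFIX <- "urn:lsid:marinespecies.org:taxname:"
LSID_RE <- "^urn:lsid:marinespecies\\.org:taxname:(\\d+)$"

#' Parse and build WoRMS-style LSIDs
#'
#' Every taxon in the taxonomic backbone carries a persistent numeric
#' AphiaID, which expands to a Life Science Identifier of the form
#' `urn:lsid:marinespecies.org:taxname:<AphiaID>`. `parse_lsid()` accepts
#' exactly that form and returns the embedded AphiaID; anything else —
#' including a bare numeric AphiaID — is rejected, with a message
#' suggesting the expansion.
#'
#' @param lsid A single LSID string.
#' @param aphia_id A positive integer AphiaID.
#' @return `parse_lsid()`: the AphiaID as an integer; `make_lsid()`: the
#'   LSID string.
#' @examples
#' parse_lsid("urn:lsid:marinespecies.org:taxname:123456")
#' make_lsid(123456)
#' @export
parse_lsid <- function(lsid) {
  if (length(lsid) != 1 || is.na(lsid)) {
    stop("LSID must be a single non-missing string", call. = FALSE)
  }
  m <- regmatches(lsid, regexec(LSID_RE, lsid))[[1]]
  if (length(m) != 2) {
    hint <- if (grepl("^\\d+$", lsid)) {
      sprintf(" ('%s' looks like a bare AphiaID; expand it to '%s%s')", lsid, LSID_PREFIX, lsid)
    } else {
      ""
    }
    stop(sprintf(
      "malformed LSID '%s': expected the form '%s<AphiaID>'%s", lsid, LSID_PREFIX, hint
    ), call. = FALSE)
  }
  as.integer(m[2])
}

#' @rdname parse_lsid
#' @export
make_lsid <- function(aphia_id) paste0(LSID_PREFIX, as.integer(aphia_id))

#' Construct or read a taxonomy store
#'
#' A taxonomy store is a keyed table of taxa, one row per AphiaID, with the
#' name, authorship, rank, acceptance flag and parent link that the
#' autopopulation and classification operations need. Parent chains must be
#' acyclic and terminate at a single root (`parent_aphia_id` = `NA`).
#'
#' @param taxa Tibble with columns `aphia_id`, `lsid`, `scientific_name`,
#'   `authorship`, `rank`, `parent_aphia_id`, `accepted`.
#' @param path Path to a `taxa.csv` fixture with those columns.
#' @return A `taxon_store` tibble.
#' @export
taxon_store <- function(taxa) {
  required <- c("aphia_id", "lsid", "scientific_name", "authorship", "rank",
                "parent_aphia_id", "accepted")
  missing <- setdiff(required, names(taxa))
  if (length(missing)) {
    stop("taxon store is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  taxa <- tibble::as_tibble(taxa)[, required]
  taxa$aphia_id <- as.integer(taxa$aphia_id)
  taxa$parent_aphia_id <- as.integer(taxa$parent_aphia_id)
  taxa$accepted <- as.logical(taxa$accepted)
  if (anyDuplicated(taxa$aphia_id)) stop("duplicate aphia_id in taxon store", call. = FALSE)
  known_parent <- is.na(taxa$parent_aphia_id) | taxa$parent_aphia_id %in% taxa$aphia_id
  if (!all(known_parent)) {
    stop("taxon store has parent_aphia_id values absent from the store", call. = FALSE)
  }
  if (sum(is.na(taxa$parent_aphia_id)) != 1 && nrow(taxa) > 0) {
    stop("taxon store must have exactly one root (parent_aphia_id = NA)", call. = FALSE)
  }
  class(taxa) <- c("taxon_store", class(taxa))
  taxa
}

#' @rdname taxon_store
#' @export
read_taxon_store <- function(path) {
  taxon_store(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname taxon_store
#' @param store A store to write.
#' @export
write_taxon_store <- function(store, path) {
  readr::write_csv(tibble::as_tibble(unclass(store)), path, na = "", progress = FALSE)
  invisible(path)
}

#' Construct or read a gazetteer store
#'
#' One row per geographic object: a unique MRGID-style `location_id`, the
#' `locality` name, and a `placetype` giving context (a sea, a bay, a
#' ridge, a sandbank, a trench, ...).
#'
#' @param regions Tibble with columns `location_id`, `locality`, `placetype`.
#' @param path Path to a `regions.csv` fixture.
#' @return A `region_store` tibble.
#' @export
region_store <- function(regions) {
  required <- c("location_id", "locality", "placetype")
  missing <- setdiff(required, names(regions))
  if (length(missing)) {
    stop("region store is missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  regions <- tibble::as_tibble(regions)[, required]
  regions$location_id <- as.character(regions$location_id)
  if (anyDuplicated(regions$location_id)) {
    stop("duplicate location_id in region store", call. = FALSE)
  }
  class(regions) <- c("region_store", class(regions))
  regions
}

#' @rdname region_store
#' @export
read_region_store <- function(path) {
  region_store(readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE, progress = FALSE
  ))
}

#' @rdname region_store
#' @param store A store to write.
#' @export
write_region_store <- function(store, path) {
  readr::write_csv(tibble::as_tibble(unclass(store)), path, na = "", progress = FALSE)
  invisible(path)
}

taxon_lookup <- function(taxa, aphia_id) {
  hit <- which(taxa$aphia_id == aphia_id)
  if (!length(hit)) return(NULL)
  taxa[hit[1], ]
}

#' Autopopulate the taxonomy fields of OTU rows
#'
#' The OTU table links to the taxonomic backbone through
#' `scientificNameID`; given that LSID, `scientificName`,
#' `scientificNameAuthorship` and `taxonRank` are filled from the store and
#' `CombinedNameID` is recomputed as scientificName + Morphospecies.
#' Pre-existing values that disagree with the store are overwritten, and
#' each overwrite is reported in the `overwrites` attribute of the result.
#' The operation is idempotent.
#'
#' @param otu One or more OTU-table rows (a tibble).
#' @param taxa A [taxon_store()].
#' @return The rows with taxonomy fields populated; attribute `overwrites`
#'   is a tibble (otu, field, old, new) of disagreeing values replaced, and
#'   attribute `unaccepted` lists OTUs resolving to unaccepted names.
#' @export
autopopulate_otu <- function(otu, taxa) {
  overwrites <- list()
  unaccepted <- character()
  misses <- character()
  for (i in seq_len(nrow(otu))) {
    lsid <- otu$scientific_name_id[i]
    aphia <- tryCatch(parse_lsid(lsid), error = function(e) NA_integer_)
    if (is.na(aphia)) {
      misses <- c(misses, sprintf("row %d: malformed LSID '%s'", i, lsid %||% NA))
      next
    }
    entry <- taxon_lookup(taxa, aphia)
    if (is.null(entry)) {
      misses <- c(misses, sprintf("row %d: AphiaID %d not in taxon store", i, aphia))
      next
    }
    ref <- otu$otu[i] %||% NA_character_
    for (field in c("scientific_name", "scientific_name_authorship", "taxon_rank")) {
      store_val <- entry[[sub("scientific_name_authorship", "authorship",
                          sub("taxon_rank", "rank", field))]]
      old <- otu[[field]][i]
      if (!is.na(old) && !identical(old, store_val)) {
        overwrites[[length(overwrites) + 1]] <- tibble::tibble(
          otu = ref, field = field, old = old, new = store_val
        )
      }
      otu[[field]][i] <- store_val
    }
    otu$combined_name_id[i] <- make_combined_name(entry$scientific_name, otu$morphospecies[i])
    if (!isTRUE(entry$accepted)) unaccepted <- c(unaccepted, ref)
  }
  if (length(misses)) {
    stop("unresolved taxa:\n  ", paste(misses, collapse = "\n  "), call. = FALSE)
  }
  attr(otu, "overwrites") <- if (length(overwrites)) {
    dplyr::bind_rows(overwrites)
  } else {
    tibble::tibble(otu = character(), field = character(), old = character(), new = character())
  }
  attr(otu, "unaccepted") <- unaccepted
  otu
}

#' Root-to-taxon classification path
#'
#' Follows parent links from the queried taxon up to the root of the store
#' and returns the chain in root-to-taxon order, so an OTU can be placed in
#' the standard taxonomic hierarchy.
#'
#' @param taxa A [taxon_store()].
#' @param aphia_id AphiaID of the taxon to classify.
#' @return Tibble with columns `aphia_id`, `rank`, `scientific_name`,
#'   ordered root first.
#' @export
classification_path <- function(taxa, aphia_id) {
  entry <- taxon_lookup(taxa, aphia_id)
  if (is.null(entry)) {
    stop(sprintf("AphiaID %s not in taxon store", aphia_id), call. = FALSE)
  }
  chain <- list()
  seen <- integer()
  while (!is.null(entry)) {
    if (entry$aphia_id %in% seen) {
      stop("corrupt taxon store: cycle in parent chain", call. = FALSE)
    }
    seen <- c(seen, entry$aphia_id)
    chain[[length(chain) + 1]] <- entry[, c("aphia_id", "rank", "scientific_name")]
    if (is.na(entry$parent_aphia_id)) break
    parent <- taxon_lookup(taxa, entry$parent_aphia_id)
    if (is.null(parent)) {
      stop(sprintf("corrupt taxon store: parent %d missing", entry$parent_aphia_id), call. = FALSE)
    }
    entry <- parent
  }
  dplyr::bind_rows(rev(chain))
}

#' Resolve a gazetteer identifier
#'
#' Looks a `locationID` up in the gazetteer store. A miss is a value, not
#' an error, so validation can aggregate misses across a catalogue. When a
#' record's locality string is supplied it is compared with the entry's
#' locality name; a mismatch is reported in the result, never silently
#' corrected.
#'
#' @param regions A [region_store()].
#' @param location_id Identifier to resolve.
#' @param locality Optional locality string to cross-check.
#' @return A list with `found` (logical), `entry` (one-row tibble or
#'   `NULL`) and `locality_match` (logical, `NA` when not checked or not
#'   found).
#' @export
resolve_region <- function(regions, location_id, locality = NULL) {
  hit <- which(regions$location_id == location_id)
  if (!length(hit)) {
    return(list(found = FALSE, entry = NULL, locality_match = NA))
  }
  entry <- regions[hit[1], ]
  match <- if (is.null(locality)) NA else identical(trimws(locality), trimws(entry$locality))
  list(found = TRUE, entry = entry, locality_match = match)
}
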
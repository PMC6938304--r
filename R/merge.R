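# Canonicalization and merging of transfer catalogues, plus the curation
# edits the standard anticipates: renaming an OTU to a better identification,
# reassigning an image to another OTU, changing verification status, and
# regional/depth/taxonomic subsetting. Identity history (PreviousName,
# previousIdentifications) only ever grows.

timestamp_now <- function(stamp = NULL) {
  stamp %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Canonicalize a transfer catalogue
#'
#' Turns a stage-1 transfer catalogue into canonical (curated-database)
#' form: assigns fresh GUIDs to rows lacking them, autopopulates the
#' taxonomy fields of every OTU row from the taxon store (recomputing
#' `CombinedNameID`), and stamps `modified`. Idempotent apart from the
#' `modified` stamp: a second pass assigns no new GUIDs and changes no
#' field. Unresolved taxa abort with the aggregated miss list.
#'
#' @param cat A catalogue (transfer or canonical mode).
#' @param taxa A [taxon_store()].
#' @param stamp Optional fixed `modified` timestamp (ISO 8601 string); by
#'   default the current UTC time. A fixed stamp makes runs reproducible.
#' @return A canonical-mode catalogue. Attribute `overwrites` reports
#'   stale taxonomy values replaced from the store.
#' @export
canonicalize <- function(cat, taxa, stamp = NULL) {
  stopifnot(is_catalogue(cat))
  stamp <- timestamp_now(stamp)
  otu <- cat$otu
  images <- cat$images
  missing_otu <- is.na(otu$number) | !nzchar(otu$number)
  if (any(missing_otu)) otu$number[missing_otu] <- new_guid(sum(missing_otu))
  missing_img <- is.na(images$number) | !nzchar(images$number)
  if (any(missing_img)) images$number[missing_img] <- new_guid(sum(missing_img))
  otu <- autopopulate_otu(otu, taxa)
  overwrites <- attr(otu, "overwrites")
  attr(otu, "overwrites") <- NULL
  attr(otu, "unaccepted") <- NULL
  images$modified <- rep(stamp, nrow(images))
  out <- new_catalogue(otu, images, image_dir = cat$image_dir,
                       source_label = cat$source_label, mode = "canonical",
                       extra = cat$extra)
  attr(out, "overwrites") <- overwrites
  out
}

otu_merge_key <- function(lsid, morphospecies) {
  paste0(lsid, "||", tolower(trimws(morphospecies)))
}

global_otu_ids <- function(n) sprintf("OTU_%03d", seq_len(n))

#' Merge catalogues into one curated catalogue with provenance
#'
#' Canonicalizes each input, then groups OTU rows across sources by the
#' matching key (`scientificNameID`, case-folded `Morphospecies`). Each
#' group becomes one global OTU with a fresh sequential identifier; image
#' rows are re-pointed through the mapping while their source provenance
#' (`collectionID`, `bibliographicCitation`, source label) is left
#' untouched. Groups disagreeing on `IdentificationFeatures` keep the
#' longest text, with the alternatives reported; the merged OTU's iconic
#' images are the union of the members'. OTUs whose combined name collides
#' with a different LSID are never merged — they are listed in the report
#' for curator attention. A curator-supplied mapping
#' (`source_label`, `source_otu`, `global_otu`) overrides key grouping.
#'
#' @param cats List of catalogues.
#' @param taxa A [taxon_store()].
#' @param mapping Optional curator mapping tibble with columns
#'   `source_label`, `source_otu`, `global_otu`.
#' @param stamp Optional fixed `modified` timestamp.
#' @return List with elements `catalogue` (the merged canonical catalogue)
#'   and `report` (a `merge_report` list: per-source counts, the total and
#'   per-source injective `otu_mapping`, combined-name collisions, and
#'   identification-features alternatives).
#' @export
merge_catalogues <- function(cats, taxa, mapping = NULL, stamp = NULL) {
  if (!length(cats)) stop("no catalogues to merge", call. = FALSE)
  stopifnot(all(vapply(cats, is_catalogue, logical(1))))
  stamp <- timestamp_now(stamp)
  cats <- lapply(cats, canonicalize, taxa = taxa, stamp = stamp)

  labels <- vapply(cats, function(c) c$source_label, character(1))
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = "#")
    for (i in seq_along(cats)) cats[[i]]$source_label <- labels[i]
  }

  all_otu <- dplyr::bind_rows(lapply(cats, function(c) {
    dplyr::mutate(c$otu, .source = c$source_label)
  }))
  all_img <- dplyr::bind_rows(lapply(cats, function(c) {
    dplyr::mutate(c$images, .source = c$source_label)
  }))

  key <- otu_merge_key(all_otu$scientific_name_id, all_otu$morphospecies)
  if (!is.null(mapping)) {
    idx <- match(paste(all_otu$.source, all_otu$otu), paste(mapping$source_label, mapping$source_otu))
    key[!is.na(idx)] <- paste0("curator||", mapping$global_otu[idx[!is.na(idx)]])
  }
  groups <- split(seq_len(nrow(all_otu)), factor(key, levels = unique(key)))
  gids <- global_otu_ids(length(groups))

  merged_rows <- vector("list", length(groups))
  feature_alternatives <- list()
  mapping_rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- all_otu[groups[[g]], ]
    base <- rows[1, setdiff(names(rows), ".source")]
    base$otu <- gids[g]
    base$number <- new_guid(1)
    feats <- unique(rows$identification_features[!is.na(rows$identification_features) &
                                                  nzchar(rows$identification_features)])
    if (length(feats) > 1) {
      keep <- feats[which.max(nchar(feats))]
      base$identification_features <- keep
      feature_alternatives[[length(feature_alternatives) + 1]] <- tibble::tibble(
        global_otu = gids[g], kept = keep,
        alternatives = list(setdiff(feats, keep))
      )
    } else if (length(feats) == 1) {
      base$identification_features <- feats
    }
    base$previous_name <- list(unique(unlist(rows$previous_name)))
    base$iconic_image <- list(unique(unlist(rows$iconic_image)))
    merged_rows[[g]] <- base
    mapping_rows[[g]] <- tibble::tibble(
      source_label = rows$.source, source_otu = rows$otu, global_otu = gids[g]
    )
  }
  merged_otu <- dplyr::bind_rows(merged_rows)
  otu_mapping <- dplyr::bind_rows(mapping_rows)

  # combined-name collisions: identical combined name, different LSID
  fold <- tolower(merged_otu$combined_name_id)
  collisions <- list()
  for (nm in unique(fold[duplicated(fold)])) {
    rows <- merged_otu[fold == nm, ]
    if (length(unique(rows$scientific_name_id)) > 1) {
      collisions[[length(collisions) + 1]] <- tibble::tibble(
        combined_name_id = rows$combined_name_id[1],
        global_otus = list(rows$otu),
        scientific_name_ids = list(unique(rows$scientific_name_id))
      )
    }
  }

  img_key <- paste(all_img$.source, all_img$otu)
  map_key <- paste(otu_mapping$source_label, otu_mapping$source_otu)
  all_img$otu <- otu_mapping$global_otu[match(img_key, map_key)]
  merged_img <- all_img[, setdiff(names(all_img), ".source")]

  report <- structure(list(
    per_source = tibble::tibble(
      source_label = labels,
      n_otus = vapply(cats, function(c) nrow(c$otu), integer(1)),
      n_images = vapply(cats, function(c) nrow(c$images), integer(1))
    ),
    otu_mapping = otu_mapping,
    collisions = if (length(collisions)) dplyr::bind_rows(collisions) else
      tibble::tibble(combined_name_id = character(), global_otus = list(),
                     scientific_name_ids = list()),
    feature_alternatives = if (length(feature_alternatives)) {
      dplyr::bind_rows(feature_alternatives)
    } else {
      tibble::tibble(global_otu = character(), kept = character(), alternatives = list())
    }
  ), class = "merge_report")

  out <- new_catalogue(merged_otu, merged_img, image_dir = cats[[1]]$image_dir,
                       source_label = "merged", mode = "canonical")
  list(catalogue = out, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("<merge report>\n")
  cat("  sources:\n")
  for (i in seq_len(nrow(x$per_source))) {
    cat(sprintf("    %s: %d OTUs, %d images\n", x$per_source$source_label[i],
                x$per_source$n_otus[i], x$per_source$n_images[i]))
  }
  cat(sprintf("  global OTUs: %d\n", length(unique(x$otu_mapping$global_otu))))
  cat(sprintf("  combined-name collisions (not merged): %d\n", nrow(x$collisions)))
  cat(sprintf("  identification-features conflicts: %d\n", nrow(x$feature_alternatives)))
  invisible(x)
}

#' Serialise a merge report to JSON
#'
#' @param report A merge report from [merge_catalogues()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_merge_report <- function(report, path) {
  jsonlite::write_json(
    list(
      per_source = report$per_source,
      otu_mapping = report$otu_mapping,
      collisions = report$collisions,
      feature_alternatives = report$feature_alternatives
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

find_otu_row <- function(cat, global_otu) {
  i <- which(cat$otu$otu == global_otu)
  if (!length(i)) stop(sprintf("unknown OTU '%s'", global_otu), call. = FALSE)
  i[1]
}

find_image_row <- function(cat, image_number) {
  i <- which(cat$images$number == image_number)
  if (!length(i)) stop(sprintf("unknown image '%s'", image_number), call. = FALSE)
  i[1]
}

#' Rename an OTU to a new identification
#'
#' When an OTU is later identified more confidently (typically to a lower
#' taxonomic rank — e.g. a family-level morphospecies resolved to a genus),
#' the old combined name is appended to `PreviousName`, the taxonomy fields
#' are re-autopopulated from the new LSID, `CombinedNameID` is recomputed
#' and `modified` is stamped on the OTU's image rows. Renaming to the
#' identical name is a no-op with a warning.
#'
#' @param cat A catalogue.
#' @param global_otu OTU identifier to rename.
#' @param new_lsid LSID of the new identification (must resolve).
#' @param new_morphospecies New morphospecies qualifier.
#' @param taxa A [taxon_store()].
#' @param stamp Optional fixed `modified` timestamp.
#' @return The edited catalogue.
#' @export
rename_otu <- function(cat, global_otu, new_lsid, new_morphospecies, taxa, stamp = NULL) {
  i <- find_otu_row(cat, global_otu)
  entry <- taxon_lookup(taxa, parse_lsid(new_lsid))
  if (is.null(entry)) {
    stop(sprintf("LSID '%s' does not resolve in the taxon store", new_lsid), call. = FALSE)
  }
  new_combined <- make_combined_name(entry$scientific_name, new_morphospecies)
  old_combined <- cat$otu$combined_name_id[i]
  if (identical(old_combined, new_combined)) {
    warning(sprintf("OTU '%s' already carries the name '%s'; nothing to do",
                    global_otu, new_combined))
    return(cat)
  }
  if (!is.na(old_combined) && nzchar(old_combined)) {
    cat$otu$previous_name[[i]] <- c(cat$otu$previous_name[[i]], old_combined)
  }
  cat$otu$scientific_name_id[i] <- new_lsid
  cat$otu$morphospecies[i] <- new_morphospecies
  cat$otu$scientific_name[i] <- entry$scientific_name
  cat$otu$scientific_name_authorship[i] <- entry$authorship
  cat$otu$taxon_rank[i] <- entry$rank
  cat$otu$combined_name_id[i] <- new_combined
  rows <- which(cat$images$otu == global_otu)
  cat$images$modified[rows] <- timestamp_now(stamp)
  cat
}

#' Reassign an image record to another OTU
#'
#' Captures a change of opinion on the identity of the organism in one
#' image: the old OTU identifier is appended to `previousIdentifications`,
#' the `OTU` link is re-pointed and `modified` is stamped. Reassigning an
#' image to the OTU it already belongs to is an error (no-op guard).
#'
#' @param cat A catalogue.
#' @param image_number GUID (`Number`) of the image record.
#' @param new_global_otu Target OTU identifier (must exist).
#' @param stamp Optional fixed `modified` timestamp.
#' @return The edited catalogue.
#' @export
reassign_image <- function(cat, image_number, new_global_otu, stamp = NULL) {
  i <- find_image_row(cat, image_number)
  find_otu_row(cat, new_global_otu)  # must exist
  old <- cat$images$otu[i]
  if (identical(old, new_global_otu)) {
    stop(sprintf("image '%s' is already assigned to OTU '%s'", image_number, new_global_otu),
         call. = FALSE)
  }
  cat$images$previous_identifications[[i]] <- c(cat$images$previous_identifications[[i]], old)
  cat$images$otu[i] <- new_global_otu
  cat$images$modified[i] <- timestamp_now(stamp)
  cat
}

#' Change the identification verification status of an image record
#'
#' The quality score of an identification (1 = from the image only, 2 =
#' image plus physical specimens from the same region, 3 = image plus that
#' specific physical specimen) normally only improves as specimens are
#' collected and identified. Upgrades are free; downgrades require
#' `force = TRUE` and are logged in `identificationRemarks`; status 3
#' always requires `PhysicalSample = Yes`.
#'
#' @param cat A catalogue.
#' @param image_number GUID (`Number`) of the image record.
#' @param new_status Integer 1, 2 or 3.
#' @param force Allow a downgrade.
#' @param stamp Optional fixed `modified` timestamp.
#' @return The edited catalogue.
#' @export
set_verification_status <- function(cat, image_number, new_status, force = FALSE, stamp = NULL) {
  if (!(new_status %in% 1:3)) {
    stop("verification status must be 1, 2 or 3", call. = FALSE)
  }
  i <- find_image_row(cat, image_number)
  old <- cat$images$identification_verification_status[i]
  if (new_status == 3L && !isTRUE(cat$images$physical_sample[i])) {
    stop("STATUS3_NOSAMPLE: status 3 requires the specific physical specimen (PhysicalSample = Yes)",
         call. = FALSE)
  }
  if (!is.na(old) && new_status < old && !force) {
    stop(sprintf("refusing to downgrade verification status %d -> %d without force", old, new_status),
         call. = FALSE)
  }
  if (!is.na(old) && new_status < old && force) {
    note <- sprintf("verification status downgraded %d -> %d", old, new_status)
    remarks <- cat$images$identification_remarks[i]
    cat$images$identification_remarks[i] <- if (is.na(remarks) || !nzchar(remarks)) {
      note
    } else {
      paste(remarks, note, sep = "; ")
    }
  }
  cat$images$identification_verification_status[i] <- as.integer(new_status)
  cat$images$modified[i] <- timestamp_now(stamp)
  cat
}

#' Subset a catalogue by region, depth and/or taxonomic subtree
#'
#' Builds a local reference catalogue: keeps the image rows matching every
#' given filter — gazetteer membership by `locationID`, depth-interval
#' overlap with `depth_range`, and membership of the OTU's classification
#' path in the subtree rooted at `taxon_subtree` — then keeps the OTU rows
#' with at least one surviving image. An empty result is legal.
#'
#' @param cat A canonical catalogue.
#' @param location_ids Character vector of `locationID`s, or `NULL`.
#' @param depth_range Numeric `c(min, max)` in metres, or `NULL`; a record
#'   is kept when its depth interval overlaps the filter interval.
#' @param taxon_subtree AphiaID of the subtree root, or `NULL`.
#' @param taxa A [taxon_store()] (needed for `taxon_subtree`).
#' @return The filtered catalogue.
#' @export
subset_catalogue <- function(cat, location_ids = NULL, depth_range = NULL,
                             taxon_subtree = NULL, taxa = NULL) {
  stopifnot(is_catalogue(cat))
  keep <- rep(TRUE, nrow(cat$images))
  if (!is.null(location_ids)) {
    keep <- keep & (cat$images$location_id %in% location_ids)
  }
  if (!is.null(depth_range)) {
    stopifnot(length(depth_range) == 2, depth_range[1] <= depth_range[2])
    overlap <- !is.na(cat$images$minimum_depth_m) & !is.na(cat$images$maximum_depth_m) &
      cat$images$minimum_depth_m <= depth_range[2] &
      cat$images$maximum_depth_m >= depth_range[1]
    keep <- keep & overlap
  }
  if (!is.null(taxon_subtree)) {
    if (is.null(taxa)) stop("taxon_subtree filtering needs a taxon store", call. = FALSE)
    in_subtree <- vapply(cat$otu$scientific_name_id, function(lsid) {
      aphia <- tryCatch(parse_lsid(lsid), error = function(e) return(NA_integer_))
      if (is.na(aphia)) return(FALSE)
      path <- classification_path(taxa, aphia)
      as.integer(taxon_subtree) %in% path$aphia_id
    }, logical(1))
    keep_otus <- cat$otu$otu[in_subtree]
    keep <- keep & (cat$images$otu %in% keep_otus)
  }
  images <- cat$images[keep, ]
  otu <- cat$otu[cat$otu$otu %in% unique(images$otu), ]
  # iconic images referencing files on dropped image rows would dangle
  for (i in seq_len(nrow(otu))) {
    rows <- which(images$otu == otu$otu[i])
    files <- as.character(unique(c(unlist(images$insitu_image_names[rows]),
                                   unlist(images$exsitu_image_names[rows]))))
    otu$iconic_image[i] <- list(intersect(otu$iconic_image[[i]], files))
  }
  new_catalogue(otu, images, image_dir = cat$image_dir,
                source_label = cat$source_label, mode = cat$mode)
}
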
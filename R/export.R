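# End products: Darwin Core Archive (occurrence core + multimedia
# extension + meta.xml descriptor), the annotation-scheme taxonomic tree
# for image annotation software, the printable HTML field guide, and
# catalogue summary statistics.

DWC_NS <- "http://rs.tdwg.org/dwc/terms/"
DCTERMS_NS <- "http://purl.org/dc/terms/"
DCTERMS_TERMS <- c("license", "rightsHolder", "accessRights", "modified",
                   "bibliographicCitation", "identifier", "type", "creator")

term_uri <- function(term) {
  ifelse(term %in% DCTERMS_TERMS, paste0(DCTERMS_NS, term), paste0(DWC_NS, term))
}

# Occurrence-core column plan: term name -> character vector of cell values.
dwca_core_columns <- function(cat) {
  otu <- cat$otu
  images <- cat$images
  j <- match(images$otu, otu$otu)
  cells <- function(x) na_to_blank(x)
  dyn <- vapply(seq_len(nrow(images)), function(i) {
    keep <- list(
      OTU = cells(images$otu[i]),
      PhysicalSample = format_boolean(images$physical_sample[i]),
      SubstrateType = format_substrate(images$substrate_type[[i]]),
      Size = format_decimal(images$size_cm[i]),
      SubstrateMethod = cells(images$substrate_method[i]),
      ProjectName = cells(images$project_name[i]),
      `Link to external database` = cells(images$external_link[i]),
      PreviousName = if (is.na(j[i])) "" else join_pipe_list(otu$previous_name[[j[i]]]),
      IconicImage = if (is.na(j[i])) "" else join_pipe_list(otu$iconic_image[[j[i]]])
    )
    keep <- keep[vapply(keep, nzchar, logical(1))]
    if (!length(keep)) "" else as.character(jsonlite::toJSON(keep, auto_unbox = TRUE))
  }, character(1))
  list(
    occurrenceID = cells(images$number),
    scientificName = cells(otu$scientific_name[j]),
    scientificNameID = cells(otu$scientific_name_id[j]),
    scientificNameAuthorship = cells(otu$scientific_name_authorship[j]),
    taxonRank = cells(otu$taxon_rank[j]),
    identificationQualifier = cells(otu$morphospecies[j]),
    taxonConceptID = cells(otu$combined_name_id[j]),
    taxonRemarks = cells(otu$identification_features[j]),
    associatedMedia = vapply(seq_len(nrow(images)), function(i) {
      join_pipe_list(c(images$insitu_image_names[[i]], images$exsitu_image_names[[i]]))
    }, character(1)),
    associatedReferences = cells(images$image_credits),
    identifiedBy = cells(images$identified_by),
    dateIdentified = cells(images$date_identified),
    identificationRemarks = cells(images$identification_remarks),
    identificationVerificationStatus = ifelse(
      is.na(images$identification_verification_status), "",
      as.character(images$identification_verification_status)
    ),
    typeStatus = cells(images$type_status),
    eventID = cells(images$raw_image),
    locality = cells(images$locality),
    locationID = cells(images$location_id),
    locationRemarks = cells(images$location_remarks),
    decimalLatitude = format_decimal(images$decimal_latitude),
    decimalLongitude = format_decimal(images$decimal_longitude),
    minimumDepthInMeters = format_decimal(images$minimum_depth_m),
    maximumDepthInMeters = format_decimal(images$maximum_depth_m),
    institutionID = cells(images$institution_id),
    collectionID = cells(images$collection_id),
    bibliographicCitation = cells(images$bibliographic_citation),
    modified = cells(images$modified),
    license = cells(images$license),
    rightsHolder = cells(images$rights_holder),
    accessRights = cells(images$access_rights),
    previousIdentifications = vapply(images$previous_identifications,
                                     join_pipe_list, character(1)),
    catalogNumber = cells(images$catalog_number),
    associatedSequences = cells(images$associated_sequences),
    habitat = cells(images$habitat),
    dynamicProperties = dyn
  )
}

dwca_multimedia_rows <- function(cat) {
  images <- cat$images
  rows <- list()
  for (i in seq_len(nrow(images))) {
    for (f in images$insitu_image_names[[i]]) {
      rows[[length(rows) + 1]] <- c(images$number[i], f, "in-situ photograph",
                                    na_to_blank(images$image_credits[i]),
                                    na_to_blank(images$license[i]))
    }
    for (f in images$exsitu_image_names[[i]]) {
      rows[[length(rows) + 1]] <- c(images$number[i], f, "ex-situ photograph",
                                    na_to_blank(images$image_credits[i]),
                                    na_to_blank(images$license[i]))
    }
  }
  rows
}

write_dwca_table <- function(path, header, rows) {
  sanitize <- function(x) gsub("[\t\r\n]", " ", x)
  lines <- c(
    paste(header, collapse = "\t"),
    vapply(rows, function(r) paste(sanitize(r), collapse = "\t"), character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
}

dwca_meta_xml <- function(core_terms, ext_terms, path) {
  doc <- xml2::xml_new_root("archive", xmlns = "http://rs.tdwg.org/dwc/text/",
                            metadata = "eml.xml")
  # column 0 is the id; remaining fields are declared at their true indices
  core_field_terms <- core_terms[-1]
  node <- xml2::xml_add_child(doc, "core",
    rowType = paste0(DWC_NS, "Occurrence"), encoding = "UTF-8",
    fieldsTerminatedBy = "\\t", linesTerminatedBy = "\\n",
    fieldsEnclosedBy = "", ignoreHeaderLines = "1"
  )
  files <- xml2::xml_add_child(node, "files")
  xml2::xml_add_child(files, "location", "occurrence.txt")
  xml2::xml_add_child(node, "id", index = "0")
  # the id column doubles as occurrenceID, declared explicitly at index 0
  xml2::xml_add_child(node, "field", index = "0", term = term_uri("occurrenceID"))
  for (k in seq_along(core_field_terms)) {
    xml2::xml_add_child(node, "field", index = as.character(k),
                        term = term_uri(core_field_terms[k]))
  }
  ext <- xml2::xml_add_child(doc, "extension",
    rowType = "http://rs.gbif.org/terms/1.0/Multimedia", encoding = "UTF-8",
    fieldsTerminatedBy = "\\t", linesTerminatedBy = "\\n",
    fieldsEnclosedBy = "", ignoreHeaderLines = "1"
  )
  files <- xml2::xml_add_child(ext, "files")
  xml2::xml_add_child(files, "location", "multimedia.txt")
  xml2::xml_add_child(ext, "coreid", index = "0")
  for (k in seq_along(ext_terms[-1])) {
    xml2::xml_add_child(ext, "field", index = as.character(k),
                        term = term_uri(ext_terms[-1][k]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Export a catalogue as a Darwin Core Archive
#'
#' Packages the catalogue as a DwC-A: an occurrence core with one row per
#' image record (joined with its OTU's taxon fields, so every field with a
#' Darwin Core mapping is emitted under its Darwin Core term), a
#' multimedia extension with one row per image file (in-situ and ex-situ
#' files as separate rows with a type tag, keyed to the core row), a
#' `meta.xml` descriptor whose declared column indices match the files
#' exactly, and a minimal `eml.xml` stub. Fields with no Darwin Core
#' equivalent are preserved losslessly in a JSON `dynamicProperties`
#' column. The archive is a standard ZIP.
#'
#' @param cat A canonical catalogue.
#' @param out_dir Output directory.
#' @param name Archive file name.
#' @return Path to the written zip, invisibly.
#' @export
export_dwca <- function(cat, out_dir, name = "dwca.zip") {
  stopifnot(is_catalogue(cat))
  if (cat$mode != "canonical") {
    stop("Darwin Core Archives are exported from canonical catalogues only; run canonicalize() first",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- file.path(tempfile("dwca_stage"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  cols <- dwca_core_columns(cat)
  core_terms <- names(cols)
  n <- nrow(cat$images)
  core_rows <- lapply(seq_len(n), function(i) {
    vapply(cols, function(col) col[i], character(1))
  })
  write_dwca_table(file.path(stage, "occurrence.txt"), core_terms, core_rows)

  ext_terms <- c("coreid", "identifier", "type", "creator", "license")
  write_dwca_table(file.path(stage, "multimedia.txt"), ext_terms,
                   dwca_multimedia_rows(cat))

  dwca_meta_xml(core_terms, ext_terms, file.path(stage, "meta.xml"))

  eml <- xml2::xml_new_root("eml:eml",
    "xmlns:eml" = "https://eml.ecoinformatics.org/eml-2.2.0",
    packageId = paste0("smartarid:", cat$source_label), system = "smartarid"
  )
  ds <- xml2::xml_add_child(eml, "dataset")
  xml2::xml_add_child(ds, "title", paste("Morphospecies reference image catalogue:",
                                         cat$source_label))
  xml2::xml_add_child(ds, "abstract",
    paste("Occurrence records from a standardised morphospecies reference image",
          "catalogue. identificationVerificationStatus encodes identification",
          "quality: 1 = identified from image only; 2 = identified from image and",
          "physical specimens sampled from the same region; 3 = identified from",
          "image and the specific physical specimen in the image."))
  xml2::write_xml(eml, file.path(stage, "eml.xml"))

  zip_path <- file.path(out_dir, name)
  write_zip(c("meta.xml", "eml.xml", "occurrence.txt", "multimedia.txt"),
            zip_path, stage)
  invisible(zip_path)
}

# --- annotation tree --------------------------------------------------------

new_tree_node <- function(label, rank) {
  list(label = label, rank = rank, children = list())
}

sort_children <- function(node) {
  if (length(node$children)) {
    labs <- vapply(node$children, function(c) c$label, character(1))
    # leaves after internal nodes at the same level, each block alphabetical
    is_leaf <- vapply(node$children, function(c) identical(c$rank, "OTU"), logical(1))
    ord <- order(is_leaf, labs, method = "radix")
    node$children <- lapply(node$children[ord], sort_children)
    names(node$children) <- NULL
  }
  node
}

#' Build the annotation-scheme taxonomic tree of a catalogue
#'
#' Takes the union of the classification paths of every OTU, attaches each
#' OTU (labelled by its combined name) as a leaf under its lowest
#' resolvable taxon, and drops internal branches with no OTU below them
#' (nodes only enter the tree on some OTU's path). Every catalogue OTU
#' appears exactly once as a leaf; sibling taxa are ordered
#' alphabetically. The tree can be written as an indented text outline or
#' as nested JSON for import into annotation software.
#'
#' @param cat A canonical catalogue with resolvable LSIDs.
#' @param taxa A [taxon_store()].
#' @return Nested node list (`label`, `rank`, `children`).
#' @export
annotation_tree <- function(cat, taxa) {
  stopifnot(is_catalogue(cat))
  root <- NULL
  for (i in seq_len(nrow(cat$otu))) {
    aphia <- parse_lsid(cat$otu$scientific_name_id[i])
    path <- classification_path(taxa, aphia)
    if (is.null(root)) {
      root <- new_tree_node(path$scientific_name[1], path$rank[1])
    } else if (!identical(root$label, path$scientific_name[1])) {
      stop("taxon store yielded multiple roots", call. = FALSE)
    }
    leaf_label <- cat$otu$combined_name_id[i]
    insert <- function(node, depth) {
      if (depth > nrow(path)) {
        node$children[[length(node$children) + 1]] <- new_tree_node(leaf_label, "OTU")
        return(node)
      }
      lab <- path$scientific_name[depth]
      hit <- 0
      for (k in seq_along(node$children)) {
        if (identical(node$children[[k]]$label, lab) &&
            !identical(node$children[[k]]$rank, "OTU")) {
          hit <- k
          break
        }
      }
      if (!hit) {
        node$children[[length(node$children) + 1]] <- new_tree_node(lab, path$rank[depth])
        hit <- length(node$children)
      }
      node$children[[hit]] <- insert(node$children[[hit]], depth + 1)
      node
    }
    root <- insert(root, 2)
  }
  if (is.null(root)) return(new_tree_node("(empty)", NA_character_))
  sort_children(root)
}

tree_to_text <- function(node, indent = 0) {
  line <- paste0(strrep("  ", indent), node$label,
                 if (!is.na(node$rank)) paste0(" [", node$rank, "]") else "")
  c(line, unlist(lapply(node$children, tree_to_text, indent = indent + 1)))
}

tree_leaves <- function(node) {
  if (identical(node$rank, "OTU")) return(node$label)
  unlist(lapply(node$children, tree_leaves))
}

#' @rdname annotation_tree
#' @param path Output file path.
#' @param format `"text"` (indented UTF-8 outline) or `"json"` (nested
#'   objects).
#' @return `export_annotation_tree()`: the tree, invisibly, after writing
#'   the file.
#' @export
export_annotation_tree <- function(cat, taxa, path, format = c("text", "json")) {
  format <- match.arg(format)
  tree <- annotation_tree(cat, taxa)
  if (format == "text") {
    writeLines(tree_to_text(tree), path, useBytes = TRUE)
  } else {
    jsonlite::write_json(tree, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(tree)
}

# --- field guide ------------------------------------------------------------

#' Per-OTU field-guide pages
#'
#' Computes the content of one guide page per OTU: the combined name, the
#' full classification path, the iconic image (falling back to the first
#' in-situ image), the identification-features text, the best (maximum)
#' verification status across the OTU's images, the depth envelope (the
#' minimum of the image minima to the maximum of the image maxima —
#' computed only from that OTU's image rows), the localities where it was
#' recorded and the image credits to display.
#'
#' @param cat A canonical catalogue.
#' @param taxa A [taxon_store()].
#' @return Tibble with one row per OTU, ordered by combined name.
#' @export
guide_pages <- function(cat, taxa) {
  stopifnot(is_catalogue(cat))
  otu <- cat$otu
  images <- cat$images
  pages <- lapply(seq_len(nrow(otu)), function(i) {
    rec <- otu[i, ]
    rows <- which(images$otu == rec$otu)
    path <- classification_path(taxa, parse_lsid(rec$scientific_name_id))
    files <- unlist(images$insitu_image_names[rows])
    iconic <- rec$iconic_image[[1]]
    tibble::tibble(
      otu = rec$otu,
      combined_name_id = rec$combined_name_id,
      classification = paste(path$scientific_name, collapse = " > "),
      phylum = if (any(path$rank == "Phylum")) {
        path$scientific_name[path$rank == "Phylum"][1]
      } else {
        "Unplaced"
      },
      iconic_image = if (length(iconic)) iconic[1] else if (length(files)) files[1] else NA_character_,
      identification_features = rec$identification_features,
      best_status = if (length(rows)) {
        max(images$identification_verification_status[rows], na.rm = TRUE)
      } else {
        NA_integer_
      },
      depth_min_m = if (length(rows)) min(images$minimum_depth_m[rows], na.rm = TRUE) else NA_real_,
      depth_max_m = if (length(rows)) max(images$maximum_depth_m[rows], na.rm = TRUE) else NA_real_,
      localities = list(sort(unique(images$locality[rows]))),
      credits = list(sort(unique(images$image_credits[rows])))
    )
  })
  out <- dplyr::bind_rows(pages)
  out[order(out$combined_name_id, method = "radix"), ]
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

guide_page_html <- function(page, image_rel, have_image) {
  status_label <- c("1 - identified from image only",
                    "2 - identified from image and regional specimens",
                    "3 - identified from image and that specific specimen")
  img_html <- if (have_image) {
    sprintf('<img src="%s" alt="%s"/>', image_rel, html_escape(page$combined_name_id))
  } else {
    '<div class="placeholder">no image available</div>'
  }
  feats <- if (is.na(page$identification_features)) "" else {
    sprintf("<p class='features'>%s</p>", html_escape(page$identification_features))
  }
  paste0(
    sprintf('<section class="otu-page" id="%s">\n', html_escape(page$otu)),
    sprintf("<h3>%s</h3>\n", html_escape(page$combined_name_id)),
    sprintf("<p class='classification'>%s</p>\n", html_escape(page$classification)),
    img_html, "\n", feats, "\n",
    "<dl>\n",
    sprintf("<dt>Identification quality</dt><dd>%s</dd>\n",
            if (is.na(page$best_status)) "unscored" else status_label[page$best_status]),
    sprintf("<dt>Depth range</dt><dd>%s-%s m</dd>\n",
            format_decimal(page$depth_min_m), format_decimal(page$depth_max_m)),
    sprintf("<dt>Recorded at</dt><dd>%s</dd>\n",
            html_escape(paste(page$localities[[1]], collapse = "; "))),
    sprintf("<dt>Image credits</dt><dd>%s</dd>\n",
            html_escape(paste(page$credits[[1]], collapse = "; "))),
    "</dl>\n</section>\n"
  )
}

#' Build a printable HTML field guide
#'
#' Renders one page per OTU, grouped by classification at `group_by` rank
#' (sections ordered alphabetically, pages within a section ordered by
#' combined name), into a self-contained HTML document plus a
#' concatenated single-page variant suitable for print. Iconic images are
#' copied alongside when the catalogue's image directory holds them; a
#' missing file renders as a placeholder with a warning, so guides still
#' build from partial archives. Output is deterministic: the same
#' catalogue and stores give byte-identical HTML.
#'
#' @param cat A canonical catalogue.
#' @param taxa A [taxon_store()].
#' @param out_dir Output directory.
#' @param group_by Rank to group sections by (default `"Phylum"`).
#' @return Named character vector of written files (`guide`, `print`),
#'   invisibly.
#' @export
build_field_guide <- function(cat, taxa, out_dir, group_by = "Phylum") {
  pages <- guide_pages(cat, taxa)
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE, recursive = TRUE)
  section_of <- vapply(seq_len(nrow(pages)), function(i) {
    path <- classification_path(taxa, parse_lsid(
      cat$otu$scientific_name_id[match(pages$otu[i], cat$otu$otu)]
    ))
    if (any(path$rank == group_by)) path$scientific_name[path$rank == group_by][1] else "Unplaced"
  }, character(1))
  sections <- sort(unique(section_of), method = "radix")

  body <- character()
  missing_files <- character()
  for (s in sections) {
    body <- c(body, sprintf("<h2>%s</h2>\n", html_escape(s)))
    for (i in which(section_of == s)) {
      page <- pages[i, ]
      have <- FALSE
      rel <- NA_character_
      if (!is.na(page$iconic_image)) {
        rel <- file.path("images", page$iconic_image)
        src <- if (!is.na(cat$image_dir)) file.path(cat$image_dir, page$iconic_image) else ""
        if (nzchar(src) && file.exists(src)) {
          file.copy(src, file.path(out_dir, rel), overwrite = TRUE)
          have <- TRUE
        } else {
          missing_files <- c(missing_files, page$iconic_image)
        }
      }
      body <- c(body, guide_page_html(page, rel, have))
    }
  }
  if (length(missing_files)) {
    warning("guide built with placeholder(s) for missing image file(s): ",
            paste(unique(missing_files), collapse = ", "), call. = FALSE)
  }
  css <- paste(
    "body{font-family:serif;max-width:50em;margin:auto}",
    ".otu-page{page-break-inside:avoid;border-top:1px solid #999;padding:1em 0}",
    ".placeholder{border:1px dashed #999;padding:2em;text-align:center;color:#666}",
    ".classification{color:#555;font-style:italic}",
    "img{max-width:100%}", sep = "\n"
  )
  skeleton <- function(title, contents) {
    paste0(
      "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
      sprintf("<title>%s</title>\n<style>\n%s\n</style>\n</head>\n<body>\n", title, css),
      sprintf("<h1>%s</h1>\n", title),
      paste(contents, collapse = ""),
      "</body>\n</html>\n"
    )
  }
  toc <- c("<nav><ul>\n",
           vapply(seq_len(nrow(pages)), function(i) {
             sprintf('<li><a href="#%s">%s</a></li>\n', html_escape(pages$otu[i]),
                     html_escape(pages$combined_name_id[i]))
           }, character(1)),
           "</ul></nav>\n")
  files <- c(
    guide = file.path(out_dir, "guide.html"),
    print = file.path(out_dir, "guide_print.html")
  )
  writeLines(skeleton("Morphospecies field guide", c(toc, body)), files["guide"],
             useBytes = TRUE, sep = "")
  writeLines(skeleton("Morphospecies field guide (print)", body), files["print"],
             useBytes = TRUE, sep = "")
  invisible(files)
}

#' Summary statistics of a catalogue
#'
#' Counts OTUs and image records, tabulates images per verification
#' status, OTUs per phylum, and the fraction of OTUs with at least one
#' status-3 (specimen-verified) image — the quantity the coordination
#' framework aims to raise over time.
#'
#' @param cat A canonical catalogue.
#' @param taxa A [taxon_store()].
#' @return List with `n_otus`, `n_images`, `status_histogram` (named
#'   integer vector over "1","2","3"), `otus_per_phylum` (tibble) and
#'   `frac_otus_status3`.
#' @export
catalogue_stats <- function(cat, taxa) {
  stopifnot(is_catalogue(cat))
  status <- cat$images$identification_verification_status
  hist <- vapply(1:3, function(s) sum(status == s, na.rm = TRUE), integer(1))
  names(hist) <- as.character(1:3)
  phylum <- vapply(seq_len(nrow(cat$otu)), function(i) {
    aphia <- tryCatch(parse_lsid(cat$otu$scientific_name_id[i]),
                      error = function(e) NA_integer_)
    if (is.na(aphia)) return("Unresolved")
    path <- classification_path(taxa, aphia)
    if (any(path$rank == "Phylum")) path$scientific_name[path$rank == "Phylum"][1] else "Unplaced"
  }, character(1))
  per_phylum <- tibble::tibble(phylum = phylum)
  per_phylum <- dplyr::count(per_phylum, .data$phylum, name = "n_otus")
  per_phylum <- dplyr::arrange(per_phylum, dplyr::desc(.data$n_otus), .data$phylum)
  status3 <- vapply(cat$otu$otu, function(o) {
    rows <- which(cat$images$otu == o)
    length(rows) > 0 && any(status[rows] == 3L, na.rm = TRUE)
  }, logical(1))
  list(
    n_otus = nrow(cat$otu),
    n_images = nrow(cat$images),
    status_histogram = hist,
    otus_per_phylum = per_phylum,
    frac_otus_status3 = if (nrow(cat$otu)) mean(status3) else 0
  )
}
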
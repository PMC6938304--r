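# End products: DwC-A structure and independent re-parse, annotation-tree
# bijection, field-guide determinism and content, summary statistics.

test_that("the Darwin Core Archive has one core row per image and one media row per file", {
  gen <- generate_small(101, n_otus = 6)
  out <- withr::local_tempdir()
  zip <- export_dwca(gen$catalogue, out)
  dw <- read_dwca_independent(zip)
  expect_identical(nrow(dw$core$data), nrow(gen$catalogue$images))
  n_files <- sum(lengths(gen$catalogue$images$insitu_image_names)) +
    sum(lengths(gen$catalogue$images$exsitu_image_names))
  expect_identical(nrow(dw$extension$data), n_files)
  # every extension row keys back to a core row
  expect_true(all(dw$extension$key %in% dw$core$key))
  # meta.xml indices match the actual columns: spot-check via the header row
  expect_identical(dw$core$header[1], "occurrenceID")
  expect_identical(dw$core$data$scientificName,
                   unname(dw$core$data[["scientificName"]]))
})

test_that("a transfer catalogue is refused by the archive exporter", {
  gen <- generate_small(102)
  expect_error(export_dwca(as_transfer(gen$catalogue), withr::local_tempdir()),
               "canonical")
})

test_that("re-parsing the archive with an independent reader recovers every mapped field", {
  gen <- generate_small(103, n_otus = 6)
  cat1 <- gen$catalogue
  out <- withr::local_tempdir()
  dw <- read_dwca_independent(export_dwca(cat1, out))
  core <- dw$core$data
  ord <- match(cat1$images$number, dw$core$key)
  expect_false(anyNA(ord))
  j <- match(cat1$images$otu, cat1$otu$otu)
  blank <- function(x) ifelse(is.na(x), "", as.character(x))
  expect_identical(core$scientificName[ord], cat1$otu$scientific_name[j])
  expect_identical(core$scientificNameID[ord], cat1$otu$scientific_name_id[j])
  expect_identical(core$taxonRank[ord], cat1$otu$taxon_rank[j])
  expect_identical(core$identificationQualifier[ord], cat1$otu$morphospecies[j])
  expect_identical(core$taxonConceptID[ord], cat1$otu$combined_name_id[j])
  expect_identical(core$taxonRemarks[ord], cat1$otu$identification_features[j])
  expect_identical(core$identifiedBy[ord], cat1$images$identified_by)
  expect_identical(core$dateIdentified[ord], blank(cat1$images$date_identified))
  expect_identical(as.integer(core$identificationVerificationStatus[ord]),
                   cat1$images$identification_verification_status)
  expect_identical(core$eventID[ord], cat1$images$raw_image)
  expect_identical(core$locality[ord], cat1$images$locality)
  expect_identical(core$locationID[ord], cat1$images$location_id)
  expect_identical(as.numeric(ifelse(core$minimumDepthInMeters[ord] == "", NA,
                                     core$minimumDepthInMeters[ord])),
                   cat1$images$minimum_depth_m)
  expect_identical(as.numeric(ifelse(core$decimalLatitude[ord] == "", NA,
                                     core$decimalLatitude[ord])),
                   cat1$images$decimal_latitude)
  expect_identical(core$institutionID[ord], cat1$images$institution_id)
  expect_identical(core$license[ord], cat1$images$license)
  expect_identical(core$rightsHolder[ord], cat1$images$rights_holder)
  expect_identical(core$accessRights[ord], cat1$images$access_rights)
  expect_identical(core$modified[ord], cat1$images$modified)
  expect_identical(core$habitat[ord], blank(cat1$images$habitat))
  media <- vapply(seq_len(nrow(cat1$images)), function(i) {
    join_pipe_list(c(cat1$images$insitu_image_names[[i]], cat1$images$exsitu_image_names[[i]]))
  }, character(1))
  expect_identical(core$associatedMedia[ord], media)
  # unmapped fields survive in dynamicProperties
  dyn <- jsonlite::fromJSON(core$dynamicProperties[ord][1])
  expect_identical(dyn$OTU, cat1$images$otu[1])
  expect_identical(dyn$PhysicalSample,
                   if (cat1$images$physical_sample[1]) "Yes" else "No")
})

test_that("in-situ and ex-situ files appear as typed multimedia rows", {
  cat1 <- fixture_catalogue()
  dw <- read_dwca_independent(export_dwca(cat1, withr::local_tempdir()))
  ext <- dw$extension$data
  expect_setequal(ext$identifier, c("a.jpg", "b.jpg", "c.jpg", "b_lab.jpg"))
  expect_identical(ext$type[ext$identifier == "b_lab.jpg"], "ex-situ photograph")
  expect_identical(unique(ext$type[ext$identifier != "b_lab.jpg"]), "in-situ photograph")
})

test_that("annotation-tree leaves are a bijection with the OTU set", {
  for (seed in c(111, 112, 113)) {
    gen <- generate_small(seed, n_otus = 7)
    tree <- annotation_tree(gen$catalogue, gen$stores$taxa)
    leaves <- smartarid:::tree_leaves(tree)
    expect_identical(sort(leaves), sort(gen$catalogue$otu$combined_name_id))
    # no internal node childless
    check_internal <- function(node) {
      if (identical(node$rank, "OTU")) return(invisible())
      expect_gt(length(node$children), 0)
      for (c in node$children) check_internal(c)
    }
    check_internal(tree)
  }
})

test_that("the tree writes as indented text and nested JSON", {
  cat1 <- fixture_catalogue()
  cat1$otu <- cat1$otu |> tibble::add_row(
    number = "44444444-5555-4666-8777-888888888888", otu = "OTU_002",
    scientific_name = "Porifera", scientific_name_id = make_lsid(558),
    scientific_name_authorship = "Grant, 1836", taxon_rank = "Phylum",
    morphospecies = "encrusting msp1", combined_name_id = "Porifera encrusting msp1",
    previous_name = list(character()), identification_features = NA_character_,
    iconic_image = list(character())
  )
  taxa <- fixture_taxa()
  out <- withr::local_tempdir()
  export_annotation_tree(cat1, taxa, file.path(out, "tree.txt"), "text")
  lines <- readLines(file.path(out, "tree.txt"))
  expect_identical(lines[1], "Animalia [Kingdom]")
  # two phylum branches, one OTU leaf under each lineage
  expect_true("  Echinodermata [Phylum]" %in% lines)
  expect_true("  Porifera [Phylum]" %in% lines)
  expect_true(any(grepl("^\\s+Brisingidae msp1 \\[OTU\\]$", lines)))
  expect_true(any(grepl("^\\s+Porifera encrusting msp1 \\[OTU\\]$", lines)))
  export_annotation_tree(cat1, taxa, file.path(out, "tree.json"), "json")
  parsed <- jsonlite::read_json(file.path(out, "tree.json"))
  expect_identical(parsed$label, "Animalia")
  expect_identical(length(parsed$children), 2L)
})

test_that("guide pages compute depth envelopes, best status and classification", {
  taxa <- fixture_taxa()
  pages <- guide_pages(fixture_catalogue(), taxa)
  expect_identical(nrow(pages), 1L)
  expect_identical(pages$depth_min_m, 900)   # min of 900-1100 and 1000-1500
  expect_identical(pages$depth_max_m, 1500)
  expect_identical(pages$best_status, 3L)
  expect_identical(pages$classification,
                   "Animalia > Echinodermata > Asteroidea > Brisingida > Brisingidae")
  expect_identical(pages$localities[[1]], "Rockall Bank")
})

test_that("the field guide is grouped, shows features verbatim, and builds deterministically", {
  gen <- generate_small(121, n_otus = 10)
  dir <- withr::local_tempdir()
  cat1 <- generate_catalogue(gen$cfg, gen$stores$taxa, gen$stores$regions, image_dir = dir)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  f1 <- build_field_guide(cat1, gen$stores$taxa, out1)
  f2 <- build_field_guide(cat1, gen$stores$taxa, out2)
  b1 <- readBin(f1["guide"], "raw", file.size(f1["guide"]))
  b2 <- readBin(f2["guide"], "raw", file.size(f2["guide"]))
  expect_identical(b1, b2)
  html <- rawToChar(b1)
  expect_identical(length(gregexpr("otu-page", html, fixed = TRUE)[[1]]) -
                     nrow(cat1$otu) >= 0, TRUE)
  # identification features appear verbatim
  for (feat in unique(cat1$otu$identification_features)) {
    expect_true(grepl(feat, html, fixed = TRUE))
  }
  # pages count equals OTU count in the print variant too
  print_html <- readLines(f1["print"], warn = FALSE)
  expect_identical(
    length(gregexpr("<section class=\"otu-page\"", paste(print_html, collapse = "\n"),
                    fixed = TRUE)[[1]]),
    nrow(cat1$otu)
  )
})

test_that("missing image files render as placeholders with a warning", {
  gen <- generate_small(122, n_otus = 4)
  expect_warning(
    files <- build_field_guide(gen$catalogue, gen$stores$taxa, withr::local_tempdir()),
    "placeholder"
  )
  html <- paste(readLines(files["guide"], warn = FALSE), collapse = "\n")
  expect_true(grepl("class=\"placeholder\"", html, fixed = TRUE))
})

test_that("catalogue statistics match a brute-force recount", {
  gen <- generate_small(131, n_otus = 9)
  cat1 <- gen$catalogue
  s <- catalogue_stats(cat1, gen$stores$taxa)
  expect_identical(s$n_otus, nrow(cat1$otu))
  expect_identical(s$n_images, nrow(cat1$images))
  expect_identical(unname(s$status_histogram),
                   vapply(1:3, function(k) {
                     sum(cat1$images$identification_verification_status == k)
                   }, integer(1)))
  expect_identical(sum(s$status_histogram), nrow(cat1$images))
  brute <- mean(vapply(cat1$otu$otu, function(o) {
    any(cat1$images$identification_verification_status[cat1$images$otu == o] == 3L)
  }, logical(1)))
  expect_identical(s$frac_otus_status3, brute)
  expect_identical(sum(s$otus_per_phylum$n_otus), nrow(cat1$otu))
  # explicit histogram case
  probe <- fixture_catalogue()
  probe$images$identification_verification_status <- c(1L, 2L)
  extra <- probe$images[2, ]
  extra$number <- c("cccccccc-0000-4000-8000-000000000003")
  extra$identification_verification_status <- 3L
  probe$images <- dplyr::bind_rows(probe$images, probe$images[1, ], extra)
  probe$images$number[3] <- "cccccccc-0000-4000-8000-000000000004"
  s2 <- catalogue_stats(probe, fixture_taxa())
  expect_identical(unname(s2$status_histogram), c(2L, 1L, 1L))
})
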
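# Shared fixtures, built in code: a small hand-written taxonomy (the
# asteroid chain Animalia > Echinodermata > Asteroidea > Brisingida >
# Brisingidae > Brisinga, plus Porifera), a matching gazetteer, and small
# generator configurations used across the suite.

fixture_taxa <- function() {
  taxon_store(tibble::tribble(
    ~aphia_id, ~scientific_name, ~authorship,          ~rank,     ~parent_aphia_id, ~accepted,
    2L,        "Animalia",       NA_character_,        "Kingdom", NA_integer_,      TRUE,
    1806L,     "Echinodermata",  "Bruguiere, 1791",    "Phylum",  2L,               TRUE,
    123082L,   "Asteroidea",     "Blainville, 1830",   "Class",   1806L,            TRUE,
    123084L,   "Brisingida",     "Fisher, 1928",       "Order",   123082L,          TRUE,
    123095L,   "Brisingidae",    "G.O. Sars, 1875",    "Family",  123084L,          TRUE,
    123210L,   "Brisinga",       "Asbjornsen, 1856",   "Genus",   123095L,          TRUE,
    558L,      "Porifera",       "Grant, 1836",        "Phylum",  2L,               TRUE,
    605178L,   "Pentagonaster",  "Gray, 1840",         "Genus",   123095L,          FALSE
  ) |> dplyr::mutate(lsid = make_lsid(aphia_id), .after = "aphia_id"))
}

fixture_regions <- function() {
  region_store(tibble::tibble(
    location_id = c("MRGID:4358", "MRGID:4673", "MRGID:5698"),
    locality = c("Rockall Bank", "Porcupine Seabight", "Hatton Bank"),
    placetype = c("sandbank", "bay", "ridge")
  ))
}

# a minimal hand-built catalogue: one brisingid OTU, two image records
fixture_catalogue <- function() {
  otu <- empty_otu_table() |> tibble::add_row(
    number = "11111111-2222-4333-8444-555555555555",
    otu = "OTU_001",
    scientific_name = "Brisingidae",
    scientific_name_id = make_lsid(123095),
    scientific_name_authorship = "G.O. Sars, 1875",
    taxon_rank = "Family",
    morphospecies = "msp1",
    combined_name_id = "Brisingidae msp1",
    previous_name = list(character()),
    identification_features = "long spiny arms held in a filter-feeding posture",
    iconic_image = list("a.jpg")
  )
  images <- empty_image_table() |> tibble::add_row(
    number = c("aaaaaaaa-0000-4000-8000-000000000001",
               "aaaaaaaa-0000-4000-8000-000000000002"),
    otu = "OTU_001",
    insitu_image_names = list("a.jpg", c("b.jpg", "c.jpg")),
    exsitu_image_names = list(character(), "b_lab.jpg"),
    physical_sample = c(FALSE, TRUE),
    image_credits = "(c) PU-DSRG",
    identified_by = "A. Sars",
    date_identified = c("2017-12-04", "1973-02-28T15:25:00"),
    identification_remarks = NA_character_,
    identification_verification_status = c(1L, 3L),
    type_status = NA_character_,
    raw_image = c("JC136_ST012_20160604T121005", "JC136_ST013_20160605T080010"),
    locality = "Rockall Bank",
    location_id = "MRGID:4358",
    location_remarks = NA_character_,
    decimal_latitude = c(57.5949, NA),
    decimal_longitude = c(-13.6875, NA),
    minimum_depth_m = c(900, 1000),
    maximum_depth_m = c(1100, 1500),
    institution_id = "PU-DSRG",
    collection_id = "PU-DSRG-CAT",
    bibliographic_citation = NA_character_,
    modified = "2018-05-04T12:01:00",
    license = "CC-BY 4.0",
    rights_holder = "PU-DSRG",
    access_rights = "free for scientific use",
    previous_identifications = list(character(), character()),
    catalog_number = c(NA, "NHMUK-000123"),
    associated_sequences = NA_character_,
    habitat = "seamount",
    substrate_type = list(
      tibble::tibble(class = c("bedrock", "sand"), percent = c(70, 30)),
      tibble::tibble(class = character(), percent = numeric())
    ),
    size_cm = c(12.5, NA),
    substrate_method = c("Wentworth", NA),
    project_name = NA_character_,
    external_link = NA_character_
  )
  new_catalogue(otu, images, source_label = "PU-DSRG", mode = "canonical")
}

small_config <- function(seed, n_otus = 5L, ...) {
  generator_config(seed = seed, n_taxa = 30L, n_regions = 5L, n_otus = n_otus,
                   images_per_otu = c(1L, 3L), ...)
}

generate_small <- function(seed, n_otus = 5L, stores = NULL, ...) {
  cfg <- small_config(seed, n_otus = n_otus, ...)
  if (is.null(stores)) stores <- generate_stores(cfg)
  list(cfg = cfg, stores = stores,
       catalogue = generate_catalogue(cfg, stores$taxa, stores$regions))
}

# Independent minimal DwC-A reader used to cross-check the exporter: parses
# meta.xml with xml2 and slices the data files purely by the declared column
# indices (no shared code with the writer).
read_dwca_independent <- function(zip_path) {
  exdir <- withr::local_tempdir(.local_envir = parent.frame())
  utils::unzip(zip_path, exdir = exdir)
  meta <- xml2::read_xml(file.path(exdir, "meta.xml"))
  xml2::xml_ns_strip(meta)
  parse_block <- function(node) {
    loc <- xml2::xml_text(xml2::xml_find_first(node, ".//files/location"))
    fields <- xml2::xml_find_all(node, ".//field")
    idx <- as.integer(xml2::xml_attr(fields, "index"))
    term <- basename(xml2::xml_attr(fields, "term"))
    lines <- readLines(file.path(exdir, loc), encoding = "UTF-8")
    cells <- strsplit(lines, "\t", fixed = TRUE)
    body <- cells[-1]
    out <- lapply(seq_along(idx), function(k) {
      vapply(body, function(r) if (idx[k] + 1 <= length(r)) r[[idx[k] + 1]] else "",
             character(1))
    })
    names(out) <- term
    key_idx <- as.integer(xml2::xml_attr(
      xml2::xml_find_first(node, ".//id | .//coreid"), "index"
    ))
    key <- vapply(body, function(r) r[[key_idx + 1]], character(1))
    list(data = tibble::as_tibble(out, .name_repair = "minimal"), key = key,
         header = cells[[1]])
  }
  list(
    core = parse_block(xml2::xml_find_first(meta, "//core")),
    extension = parse_block(xml2::xml_find_first(meta, "//extension"))
  )
}

expect_no_errors <- function(issues) {
  expect_identical(sum(issues$severity == "error"), 0L)
}

error_multiset <- function(issues) {
  err <- issues[issues$severity == "error", c("rule_code", "table", "record_ref")]
  err[order(err$rule_code, err$table, err$record_ref, method = "radix"), ]
}

gt_multiset <- function(gt) {
  gt <- gt[, c("rule_code", "table", "record_ref")]
  gt[order(gt$rule_code, gt$table, gt$record_ref, method = "radix"), ]
}
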
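# Canonicalization, merging and curation edits: GUID assignment,
# conservation laws, order-invariance, identity-history growth, subsetting.

test_that("canonicalize assigns GUIDs, autopopulates and is idempotent", {
  gen <- generate_small(51)
  transfer <- as_transfer(gen$catalogue)
  expect_true(all(is.na(transfer$otu$number)))
  set.seed(1)
  canon <- canonicalize(transfer, gen$stores$taxa, stamp = "2020-06-01T00:00:00")
  expect_identical(canon$mode, "canonical")
  expect_false(anyNA(canon$otu$number))
  expect_identical(anyDuplicated(canon$otu$number), 0L)
  expect_false(anyNA(canon$images$number))
  expect_identical(canon$otu$scientific_name, gen$catalogue$otu$scientific_name)
  expect_identical(canon$otu$combined_name_id, gen$catalogue$otu$combined_name_id)
  expect_no_errors(validate_catalogue(canon, gen$stores$taxa, gen$stores$regions))
  again <- canonicalize(canon, gen$stores$taxa, stamp = "2020-06-02T00:00:00")
  expect_identical(again$otu, canon$otu)
  expect_identical(
    dplyr::select(again$images, -"modified"),
    dplyr::select(canon$images, -"modified")
  )
})

test_that("canonicalize overwrites stale names from the store and reports them", {
  gen <- generate_small(52)
  stale <- as_transfer(gen$catalogue)
  stale$otu$scientific_name[1] <- "Wrongname"
  canon <- canonicalize(stale, gen$stores$taxa, stamp = "2020-06-01T00:00:00")
  expected <- autopopulate_otu(stale$otu, gen$stores$taxa)
  expect_identical(canon$otu$scientific_name, expected$scientific_name)
  ow <- attr(canon, "overwrites")
  expect_identical(ow$old, "Wrongname")
})

test_that("merging groups OTUs by (LSID, case-folded morphospecies) and keeps provenance", {
  stores <- generate_stores(small_config(61))
  a <- generate_catalogue(small_config(61, n_otus = 6), stores$taxa, stores$regions)
  b <- generate_catalogue(small_config(62, n_otus = 6), stores$taxa, stores$regions)
  a$source_label <- "groupA"
  b$source_label <- "groupB"
  res <- merge_catalogues(list(a, b), stores$taxa, stamp = "2021-01-01T00:00:00")
  m <- res$catalogue

  # conservation: image rows are never created or lost
  expect_identical(nrow(m$images), nrow(a$images) + nrow(b$images))
  # mapping is total and injective per source
  expect_identical(nrow(res$report$otu_mapping), nrow(a$otu) + nrow(b$otu))
  per_source <- split(res$report$otu_mapping$source_otu, res$report$otu_mapping$source_label)
  for (s in per_source) expect_identical(anyDuplicated(s), 0L)
  # no invented OTU keys
  in_keys <- unique(c(
    smartarid:::otu_merge_key(a$otu$scientific_name_id, a$otu$morphospecies),
    smartarid:::otu_merge_key(b$otu$scientific_name_id, b$otu$morphospecies)
  ))
  out_keys <- smartarid:::otu_merge_key(m$otu$scientific_name_id, m$otu$morphospecies)
  expect_true(all(out_keys %in% in_keys))
  # provenance columns untouched
  expect_setequal(unique(m$images$collection_id),
                  unique(c(a$images$collection_id, b$images$collection_id)))
  expect_no_errors(validate_catalogue(m, stores$taxa, stores$regions))

  # shared keys collapse to one global OTU with images from both sources
  shared <- intersect(
    smartarid:::otu_merge_key(a$otu$scientific_name_id, a$otu$morphospecies),
    smartarid:::otu_merge_key(b$otu$scientific_name_id, b$otu$morphospecies)
  )
  if (length(shared)) {
    g <- res$report$otu_mapping$global_otu[match(shared[1], out_keys)]
    expect_gte(length(unique(res$report$otu_mapping$source_label[
      res$report$otu_mapping$global_otu == g
    ])), 1L)
  }
})

test_that("two sources sharing an OTU key collapse into one OTU with pooled images", {
  stores <- list(taxa = fixture_taxa(), regions = fixture_regions())
  a <- fixture_catalogue()
  a$source_label <- "groupA"
  b <- fixture_catalogue()
  b$source_label <- "groupB"
  b$otu$morphospecies[1] <- "MSP1"  # case-folded match
  b$otu$combined_name_id[1] <- "Brisingidae MSP1"
  b$images$number <- c("bbbbbbbb-0000-4000-8000-000000000001",
                       "bbbbbbbb-0000-4000-8000-000000000002")
  res <- merge_catalogues(list(a, b), stores$taxa, stamp = "2021-01-01T00:00:00")
  expect_identical(nrow(res$catalogue$otu), 1L)
  expect_identical(nrow(res$catalogue$images), 4L)
  expect_identical(unique(res$catalogue$images$otu), res$catalogue$otu$otu)
})

test_that("merge order does not change OTU keys or image multisets", {
  stores <- generate_stores(small_config(71))
  a <- generate_catalogue(small_config(71, n_otus = 5), stores$taxa, stores$regions)
  b <- generate_catalogue(small_config(72, n_otus = 5), stores$taxa, stores$regions)
  a$source_label <- "groupA"
  b$source_label <- "groupB"
  ab <- merge_catalogues(list(a, b), stores$taxa, stamp = "2021-01-01T00:00:00")$catalogue
  ba <- merge_catalogues(list(b, a), stores$taxa, stamp = "2021-01-01T00:00:00")$catalogue
  key <- function(m) sort(smartarid:::otu_merge_key(m$otu$scientific_name_id, m$otu$morphospecies))
  expect_identical(key(ab), key(ba))
  # image multiset per OTU key, identified by raw_image event ids
  imgs_by_key <- function(m) {
    k <- smartarid:::otu_merge_key(m$otu$scientific_name_id, m$otu$morphospecies)
    names(k) <- m$otu$otu
    split(m$images$raw_image, unname(k[m$images$otu])) |> lapply(sort)
  }
  expect_identical(imgs_by_key(ab), imgs_by_key(ba))
})

test_that("merging a single catalogue is canonicalization up to OTU renumbering", {
  gen <- generate_small(81)
  transfer <- as_transfer(gen$catalogue)
  set.seed(2)
  single <- merge_catalogues(list(transfer), gen$stores$taxa,
                             stamp = "2021-01-01T00:00:00")$catalogue
  set.seed(2)
  canon <- canonicalize(transfer, gen$stores$taxa, stamp = "2021-01-01T00:00:00")
  drop_ids <- function(x) {
    x$otu$number <- NULL
    x$otu$otu <- NULL
    x$images$number <- NULL
    x$images$otu <- NULL
    list(otu = x$otu[order(x$otu$combined_name_id), ], images = x$images)
  }
  expect_identical(drop_ids(single), drop_ids(canon))
})

test_that("combined-name collisions with different LSIDs are kept apart and reported", {
  # a homonym: two backbone entries spelled identically under different ids
  taxa_tbl <- tibble::as_tibble(unclass(fixture_taxa()))
  taxa_tbl <- dplyr::bind_rows(taxa_tbl, tibble::tibble(
    aphia_id = 900001L, lsid = make_lsid(900001), scientific_name = "Brisingidae",
    authorship = "Homonym, 1900", rank = "Family", parent_aphia_id = 123084L,
    accepted = TRUE
  ))
  taxa <- taxon_store(taxa_tbl)
  a <- fixture_catalogue()
  a$source_label <- "groupA"
  b <- fixture_catalogue()
  b$source_label <- "groupB"
  # same combined name text, different backbone link
  b$otu$scientific_name_id[1] <- make_lsid(900001)
  b$images$number <- c("bbbbbbbb-0000-4000-8000-000000000001",
                       "bbbbbbbb-0000-4000-8000-000000000002")
  res <- merge_catalogues(list(a, b), taxa, stamp = "2021-01-01T00:00:00")
  expect_identical(nrow(res$catalogue$otu), 2L)
  expect_identical(nrow(res$report$collisions), 1L)
  expect_identical(res$report$collisions$combined_name_id[1], "Brisingidae msp1")
})

test_that("conflicting identification features keep the longest text and report the rest", {
  taxa <- fixture_taxa()
  a <- fixture_catalogue()
  a$source_label <- "groupA"
  b <- fixture_catalogue()
  b$source_label <- "groupB"
  b$otu$identification_features[1] <- "short note"
  b$images$number <- c("bbbbbbbb-0000-4000-8000-000000000001",
                       "bbbbbbbb-0000-4000-8000-000000000002")
  res <- merge_catalogues(list(a, b), taxa, stamp = "2021-01-01T00:00:00")
  expect_identical(res$catalogue$otu$identification_features[1],
                   a$otu$identification_features[1])
  expect_identical(res$report$feature_alternatives$alternatives[[1]], "short note")
})

test_that("renaming an OTU records the previous combined name, in order", {
  taxa <- fixture_taxa()
  cat1 <- fixture_catalogue()
  renamed <- rename_otu(cat1, "OTU_001", make_lsid(123210), "msp4", taxa,
                        stamp = "2021-02-01T00:00:00")
  expect_identical(renamed$otu$combined_name_id[1], "Brisinga msp4")
  expect_identical(renamed$otu$scientific_name[1], "Brisinga")
  expect_identical(renamed$otu$taxon_rank[1], "Genus")
  expect_identical(renamed$otu$previous_name[[1]], "Brisingidae msp1")
  expect_no_errors(validate_catalogue(renamed, taxa, fixture_regions()))
  twice <- rename_otu(renamed, "OTU_001", make_lsid(123095), "msp9", taxa,
                      stamp = "2021-02-02T00:00:00")
  expect_identical(twice$otu$previous_name[[1]], c("Brisingidae msp1", "Brisinga msp4"))
  expect_warning(rename_otu(twice, "OTU_001", make_lsid(123095), "msp9", taxa),
                 "nothing to do")
  expect_error(rename_otu(cat1, "OTU_001", make_lsid(424242), "msp1", taxa), "resolve")
  expect_error(rename_otu(cat1, "OTU_404", make_lsid(123210), "msp4", taxa), "unknown OTU")
})

test_that("reassigning an image grows previousIdentifications and guards no-ops", {
  taxa <- fixture_taxa()
  cat1 <- fixture_catalogue()
  cat1$otu <- cat1$otu |> tibble::add_row(
    number = "33333333-4444-4555-8666-777777777777", otu = "OTU_002",
    scientific_name = "Porifera", scientific_name_id = make_lsid(558),
    scientific_name_authorship = "Grant, 1836", taxon_rank = "Phylum",
    morphospecies = "encrusting msp1", combined_name_id = "Porifera encrusting msp1",
    previous_name = list(character()), identification_features = NA_character_,
    iconic_image = list(character())
  )
  img <- cat1$images$number[1]
  moved <- reassign_image(cat1, img, "OTU_002", stamp = "2021-03-01T00:00:00")
  expect_identical(moved$images$otu[1], "OTU_002")
  expect_identical(moved$images$previous_identifications[[1]], "OTU_001")
  back <- reassign_image(moved, img, "OTU_001", stamp = "2021-03-02T00:00:00")
  expect_identical(back$images$previous_identifications[[1]], c("OTU_001", "OTU_002"))
  expect_error(reassign_image(back, img, "OTU_001"), "already assigned")
  expect_error(reassign_image(cat1, "no-such-guid", "OTU_002"), "unknown image")
})

test_that("verification status upgrades freely, downgrades only with force", {
  cat1 <- fixture_catalogue()
  img1 <- cat1$images$number[1]  # status 1, no specimen
  img2 <- cat1$images$number[2]  # status 3, specimen
  up <- set_verification_status(cat1, img1, 2L, stamp = "2021-04-01T00:00:00")
  expect_identical(up$images$identification_verification_status[1], 2L)
  expect_error(set_verification_status(cat1, img1, 3L), "STATUS3_NOSAMPLE")
  with_sample <- cat1
  with_sample$images$physical_sample[1] <- TRUE
  up3 <- set_verification_status(with_sample, img1, 3L, stamp = "2021-04-01T00:00:00")
  expect_identical(up3$images$identification_verification_status[1], 3L)
  expect_error(set_verification_status(cat1, img2, 1L), "downgrade")
  forced <- set_verification_status(cat1, img2, 1L, force = TRUE,
                                    stamp = "2021-04-01T00:00:00")
  expect_identical(forced$images$identification_verification_status[2], 1L)
  expect_match(forced$images$identification_remarks[2], "downgraded 3 -> 1")
})

test_that("history fields never shrink under curation edits", {
  gen <- generate_small(91, n_otus = 6)
  cat1 <- gen$catalogue
  taxa <- gen$stores$taxa
  hist_len <- function(c) {
    c(sum(lengths(c$otu$previous_name)), sum(lengths(c$images$previous_identifications)))
  }
  set.seed(7)
  current <- cat1
  for (step in 1:25) {
    before <- hist_len(current)
    op <- sample(c("rename", "reassign", "status"), 1)
    current <- tryCatch(switch(op,
      rename = {
        i <- sample(nrow(current$otu), 1)
        tx <- smartarid:::resample(which(!is.na(taxa$parent_aphia_id)), 1)
        rename_otu(current, current$otu$otu[i], taxa$lsid[tx],
                   paste0("msp", sample(50:99, 1)), taxa, stamp = "2021-05-01T00:00:00")
      },
      reassign = {
        i <- sample(nrow(current$images), 1)
        targets <- setdiff(current$otu$otu, current$images$otu[i])
        reassign_image(current, current$images$number[i],
                       smartarid:::resample(targets, 1), stamp = "2021-05-01T00:00:00")
      },
      status = {
        i <- sample(nrow(current$images), 1)
        set_verification_status(current, current$images$number[i],
                                sample(1:3, 1), force = TRUE,
                                stamp = "2021-05-01T00:00:00")
      }
    ), error = function(e) current, warning = function(w) current)
    expect_true(all(hist_len(current) >= before))
  }
})

test_that("subsetting filters by region, overlapping depth interval and taxon subtree", {
  gen <- generate_small(95, n_otus = 8)
  cat1 <- gen$catalogue
  stores <- gen$stores
  lid <- cat1$images$location_id[1]
  by_region <- subset_catalogue(cat1, location_ids = lid)
  expect_identical(nrow(by_region$images), sum(cat1$images$location_id == lid))
  expect_setequal(by_region$otu$otu, unique(by_region$images$otu))
  expect_no_errors(validate_catalogue(by_region, stores$taxa, stores$regions))

  # interval-overlap semantics, brute-forced over all rows
  rng <- c(800, 1200)
  by_depth <- subset_catalogue(cat1, depth_range = rng)
  brute <- vapply(seq_len(nrow(cat1$images)), function(i) {
    cat1$images$minimum_depth_m[i] <= rng[2] && cat1$images$maximum_depth_m[i] >= rng[1]
  }, logical(1))
  expect_identical(by_depth$images$number, cat1$images$number[brute])

  # a row overlapping only partially is still kept
  probe <- fixture_catalogue()
  kept <- subset_catalogue(probe, depth_range = c(800, 1200))
  expect_identical(nrow(kept$images), 2L)  # 900-1100 and 1000-1500 both overlap
  expect_identical(nrow(subset_catalogue(probe, depth_range = c(1, 2))$images), 0L)

  # taxon subtree: brute-force path membership
  root2 <- stores$taxa$aphia_id[stores$taxa$rank == "Phylum"][1]
  by_taxon <- subset_catalogue(cat1, taxon_subtree = root2, taxa = stores$taxa)
  brute_in <- vapply(cat1$otu$scientific_name_id, function(l) {
    root2 %in% classification_path(stores$taxa, parse_lsid(l))$aphia_id
  }, logical(1))
  expect_setequal(by_taxon$otu$otu, cat1$otu$otu[brute_in])
  expect_no_errors(validate_catalogue(by_taxon, stores$taxa, stores$regions))
})
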
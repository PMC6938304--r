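# Deterministic synthetic fixtures: taxonomy and gazetteer stores, clean
# catalogues, and ground-truth-labelled violation injection, so every module
# is testable offline and reproducibly. The generator mimics the conventions
# of real catalogues (morphospecies strings "msp<k>" with occasional growth
# forms, RawImage "CruiseNumber_StationNumber_timestamp" event identifiers,
# North Atlantic deep-sea depths and coordinates) but makes no attempt to
# mimic real taxon-name frequencies or real imagery.

GEN_RANKS <- c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus", "Species")
GEN_PHYLA <- c("Porifera", "Cnidaria", "Echinodermata", "Arthropoda",
               "Mollusca", "Annelida", "Bryozoa", "Chordata")
GEN_PLACETYPES <- c("sea", "bay", "ridge", "sandbank", "trench")
GEN_GROWTH_FORMS <- c("encrusting", "branching", "massive", "vase", "lobate")
GEN_HABITATS <- c("seamount", "canyon", "mid-ocean ridge", "abyssal hill",
                  "continental slope", "hydrothermal vent")
GEN_WENTWORTH <- c("boulder", "cobble", "pebble", "granule", "sand", "mud", "bedrock")
GEN_INSTITUTIONS <- c("PU-DSRG", "NUIG-ZOO", "NOC-DEEPSEA", "IMR-BENTHIC", "AZO-OKEANOS")
GEN_IDENTIFIERS <- c("A. Sars", "E. Forbes", "J. Murray", "C. W. Thomson", "M. Rathbun")
GEN_LICENSES <- c("CC-BY 4.0", "CC-BY-NC 4.0", "CC0 1.0")
GEN_PROJECTS <- c("DeepMap", "AtlantEco", "SeamountLife", NA, NA)
GEN_FEATURES <- c(
  "fan-shaped colony with regular dichotomous branching",
  "stalked body with whorls of long flexible arms held aloft",
  "thick encrusting sheet with scattered oscula on low mounds",
  "solitary polyp on a long slender peduncle",
  "dense cluster of translucent zooids with visible lophophores",
  "globular test with long primary spines and banded colouring",
  "flabellate growth form, surface with fine reticulate ridges",
  "five slender arms, disc small, arm spines arranged in combs"
)
GEN_SYLLABLES <- c("bathy", "abysso", "lopho", "ceras", "nema", "stella", "ophio",
                   "acantho", "pleuro", "doris", "crino", "thalasso", "pecten",
                   "gorgo", "actin", "hydro", "spongi", "madre", "calyx", "pila")

# sample() that never falls into the scalar 1:x trap
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

synth_name <- function(n) {
  first <- sample(GEN_SYLLABLES, n, replace = TRUE)
  second <- sample(GEN_SYLLABLES, n, replace = TRUE)
  paste0(toupper(substr(first, 1, 1)), substr(first, 2, nchar(first)), second)
}

synth_authorship <- function(n) {
  surnames <- c("Verrill", "Koehler", "Topsent", "Carter", "Mortensen", "Sars", "Danielssen")
  sprintf("(%s, %d)", sample(surnames, n, replace = TRUE),
          sample(1830:1980, n, replace = TRUE))
}

#' Configuration for the synthetic-fixture generator
#'
#' Bundles every knob of the generator with defaults shaped like a small
#' single-group submission: a taxonomy of 60 taxa over the seven Linnean
#' ranks, 8 gazetteer regions, 15 OTUs with 1-3 example images each,
#' deep-sea depths (200-2500 m), a 30% chance of an accompanying ex-situ
#' image, a 25% chance of a physical sample, and identification quality
#' scores distributed 60/25/15% over statuses 1/2/3 (most image-based
#' identifications are unverified by specimens).
#'
#' @param seed Integer seed; every generator operation is deterministic
#'   given the config.
#' @param n_taxa,tree_depth Taxonomy size and number of ranks (from
#'   Kingdom downward, at most 7).
#' @param n_regions Number of gazetteer entries.
#' @param n_otus Number of OTUs in a generated catalogue.
#' @param images_per_otu Integer `c(min, max)` image rows per OTU.
#' @param p_exsitu Probability an image row carries an ex-situ image.
#' @param p_physical_sample Probability of a physical specimen for rows
#'   whose status does not already require one.
#' @param status_weights Probabilities over verification statuses 1, 2, 3;
#'   must sum to 1.
#' @param depth_range_m Numeric `c(min, max)` depth envelope in metres.
#' @param violation_spec Named integer vector of violations to inject
#'   (rule code -> count), or `NULL`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_taxa = 60L, tree_depth = 7L,
                             n_regions = 8L, n_otus = 15L,
                             images_per_otu = c(1L, 3L), p_exsitu = 0.3,
                             p_physical_sample = 0.25,
                             status_weights = c(0.6, 0.25, 0.15),
                             depth_range_m = c(200, 2500),
                             violation_spec = NULL) {
  stopifnot(
    tree_depth >= 2, tree_depth <= length(GEN_RANKS), n_taxa >= tree_depth,
    length(images_per_otu) == 2, images_per_otu[1] >= 1,
    images_per_otu[1] <= images_per_otu[2],
    p_exsitu >= 0, p_exsitu <= 1, p_physical_sample >= 0, p_physical_sample <= 1,
    length(status_weights) == 3, all(status_weights >= 0),
    abs(sum(status_weights) - 1) < 1e-8,
    length(depth_range_m) == 2, depth_range_m[1] > 0,
    depth_range_m[1] < depth_range_m[2]
  )
  structure(list(
    seed = as.integer(seed), n_taxa = as.integer(n_taxa),
    tree_depth = as.integer(tree_depth), n_regions = as.integer(n_regions),
    n_otus = as.integer(n_otus), images_per_otu = as.integer(images_per_otu),
    p_exsitu = p_exsitu, p_physical_sample = p_physical_sample,
    status_weights = status_weights, depth_range_m = depth_range_m,
    violation_spec = violation_spec
  ), class = "generator_config")
}

#' Generate offline taxonomy and gazetteer stores
#'
#' Builds a rooted taxonomic tree with ranks assigned top-down (Kingdom at
#' the root, then Phylum, Class, ...), acyclic parent links and valid
#' LSIDs, and a gazetteer with unique MRGID-style identifiers and
#' placetypes drawn from the standard vocabulary (sea, bay, ridge,
#' sandbank, trench). About 5% of non-root taxa are flagged unaccepted to
#' exercise synonymy reporting.
#'
#' @param cfg A [generator_config()].
#' @return List with elements `taxa` (a [taxon_store()]) and `regions`
#'   (a [region_store()]).
#' @export
generate_stores <- function(cfg) {
  set.seed(cfg$seed)
  depth <- cfg$tree_depth
  n <- cfg$n_taxa
  ranks <- GEN_RANKS[seq_len(depth)]
  level <- integer(n)
  parent_idx <- rep(NA_integer_, n)
  level[1] <- 1L
  # a guaranteed spine down to the deepest rank, then random attachment
  for (i in seq_len(depth - 1)) {
    level[i + 1] <- i + 1L
    parent_idx[i + 1] <- i
  }
  if (n > depth) {
    for (i in (depth + 1):n) {
      lv <- sample(2:depth, 1)
      candidates <- which(level[seq_len(i - 1)] == lv - 1L)
      parent_idx[i] <- resample(candidates, 1)
      level[i] <- lv
    }
  }
  name <- character(n)
  name[1] <- "Animalia"
  phyla_pool <- sample(GEN_PHYLA)
  n_phyla <- 0L
  for (i in seq_len(n)[-1]) {
    if (level[i] == 2L && n_phyla < length(phyla_pool)) {
      n_phyla <- n_phyla + 1L
      name[i] <- phyla_pool[n_phyla]
    } else if (level[i] == depth && depth == length(GEN_RANKS)) {
      name[i] <- paste(name[parent_idx[i]], tolower(synth_name(1)))
    } else {
      name[i] <- synth_name(1)
    }
  }
  # uniquify any colliding synthetic names
  while (anyDuplicated(name)) {
    d <- which(duplicated(name))
    name[d] <- paste0(name[d], sample(letters, length(d), replace = TRUE))
  }
  aphia <- sample(100000:999999, n)
  accepted <- rep(TRUE, n)
  if (n > 10) {
    accepted[sample(2:n, max(1, round(0.05 * n)))] <- FALSE
  }
  taxa <- taxon_store(tibble::tibble(
    aphia_id = aphia,
    lsid = make_lsid(aphia),
    scientific_name = name,
    authorship = synth_authorship(n),
    rank = ranks[level],
    parent_aphia_id = ifelse(is.na(parent_idx), NA_integer_, aphia[parent_idx]),
    accepted = accepted
  ))
  region_names <- c("Rockall Bank", "Porcupine Seabight", "Hatton Bank",
                    "Charlie-Gibbs Fracture Zone", "Anton Dohrn Seamount",
                    "Whittard Canyon", "Rosemary Bank", "George Bligh Bank",
                    "Wyville Thomson Ridge", "Faroe-Shetland Channel",
                    "Josephine Seamount", "Gorringe Bank")
  m <- cfg$n_regions
  locality <- if (m <= length(region_names)) {
    sample(region_names, m)
  } else {
    c(region_names, paste(synth_name(m - length(region_names)), "Bank"))
  }
  regions <- region_store(tibble::tibble(
    location_id = sprintf("MRGID:%d", sample(10000:99999, m)),
    locality = locality,
    placetype = sample(GEN_PLACETYPES, m, replace = TRUE)
  ))
  list(taxa = taxa, regions = regions)
}

# deterministic modified stamps: fixed base time advanced per row
gen_stamp <- function(i) {
  format(as.POSIXct("2018-05-04 12:00:00", tz = "UTC") + 60 * i,
         "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Generate a clean canonical catalogue
#'
#' Draws OTUs over accepted taxa of the store, morphospecies qualifiers of
#' the conventional form (`msp1`, `encrusting msp1`, ...) unique within
#' each taxon, and image rows with ordered depth pairs, gazetteer-backed
#' localities, event identifiers of the form
#' `CruiseNumber_StationNumber_timestamp`, and verification statuses drawn
#' from the configured weights under the constraint that status 3 implies
#' a physical sample. The output is a canonical-mode catalogue that passes
#' validation with zero errors.
#'
#' @param cfg A [generator_config()].
#' @param taxa,regions Stores from [generate_stores()].
#' @param image_dir Optional directory; when given, 1-pixel placeholder
#'   PNG files are materialized for every referenced image so
#'   file-existence checks can run.
#' @return A canonical catalogue.
#' @export
generate_catalogue <- function(cfg, taxa, regions, image_dir = NA_character_) {
  set.seed(cfg$seed + 1L)
  n_otus <- cfg$n_otus
  pool <- which(!is.na(taxa$parent_aphia_id) & taxa$accepted)
  if (!length(pool)) stop("taxon store has no accepted non-root taxa", call. = FALSE)
  taxon_idx <- resample(pool, n_otus, replace = n_otus > length(pool))
  msp_counter <- new.env(parent = emptyenv())
  morphospecies <- vapply(seq_len(n_otus), function(i) {
    key <- as.character(taxa$aphia_id[taxon_idx[i]])
    k <- (get0(key, msp_counter) %||% 0L) + 1L
    assign(key, k, msp_counter)
    if (stats::runif(1) < 0.2) {
      paste(sample(GEN_GROWTH_FORMS, 1), paste0("msp", k))
    } else {
      paste0("msp", k)
    }
  }, character(1))
  otu_ids <- sprintf("OTU_%03d", seq_len(n_otus))
  otu <- tibble::tibble(
    number = new_guid(n_otus),
    otu = otu_ids,
    scientific_name = taxa$scientific_name[taxon_idx],
    scientific_name_id = taxa$lsid[taxon_idx],
    scientific_name_authorship = taxa$authorship[taxon_idx],
    taxon_rank = taxa$rank[taxon_idx],
    morphospecies = morphospecies,
    combined_name_id = make_combined_name(taxa$scientific_name[taxon_idx], morphospecies),
    previous_name = replicate(n_otus, character(), simplify = FALSE),
    identification_features = sample(GEN_FEATURES, n_otus, replace = TRUE),
    iconic_image = replicate(n_otus, character(), simplify = FALSE)
  )

  n_img_per <- resample(seq(cfg$images_per_otu[1], cfg$images_per_otu[2]),
                        n_otus, replace = TRUE)
  n_img <- sum(n_img_per)
  img_otu <- rep(otu_ids, n_img_per)
  file_id <- sample(10000:99999, n_img)
  insitu <- sprintf("IMG%05d.jpg", file_id)
  has_exsitu <- stats::runif(n_img) < cfg$p_exsitu
  exsitu <- ifelse(has_exsitu, sprintf("IMG%05d_lab.jpg", file_id), NA_character_)
  status <- sample(1:3, n_img, replace = TRUE, prob = cfg$status_weights)
  physical <- status == 3L | stats::runif(n_img) < cfg$p_physical_sample
  region_idx <- sample.int(nrow(regions), n_img, replace = TRUE)
  d1 <- round(stats::runif(n_img, cfg$depth_range_m[1], cfg$depth_range_m[2]), 1)
  spread <- round(stats::runif(n_img, 0, 300), 1)
  exact <- stats::runif(n_img) < 0.2
  dmin <- pmin(d1, round(pmax(cfg$depth_range_m[1], d1 - spread), 1))
  dmax <- ifelse(exact, dmin, round(d1, 1))
  dmin2 <- pmin(dmin, dmax)
  dmax2 <- pmax(dmin, dmax)
  has_coord <- stats::runif(n_img) < 0.7
  institution <- sample(GEN_INSTITUTIONS, n_img, replace = TRUE)
  cruise <- sprintf("JC%03d", sample(10:250, n_img, replace = TRUE))
  station <- sprintf("ST%03d", sample(1:400, n_img, replace = TRUE))
  event_time <- format(
    as.POSIXct("2016-06-01 00:00:00", tz = "UTC") + sample(0:(2 * 365 * 86400), n_img),
    "%Y%m%dT%H%M%S"
  )
  has_date_ident <- stats::runif(n_img) < 0.8
  date_only <- stats::runif(n_img) < 0.5
  ident_date <- format(as.Date("2017-01-01") + sample(0:600, n_img, replace = TRUE))
  ident_datetime <- paste0(ident_date, "T", sprintf("%02d:%02d:00",
                           sample(8:18, n_img, replace = TRUE),
                           sample(0:59, n_img, replace = TRUE)))
  has_substrate <- stats::runif(n_img) < 0.6
  substrate <- lapply(seq_len(n_img), function(i) {
    if (!has_substrate[i]) {
      return(tibble::tibble(class = character(), percent = numeric()))
    }
    k <- sample(1:2, 1)
    cls <- sample(GEN_WENTWORTH, k)
    pct <- if (k == 1) {
      if (stats::runif(1) < 0.3) NA_real_ else 100
    } else {
      p <- sample(seq(10, 90, by = 10), 1)
      c(p, 100 - p)
    }
    tibble::tibble(class = cls, percent = as.numeric(pct))
  })
  images <- tibble::tibble(
    number = new_guid(n_img),
    otu = img_otu,
    insitu_image_names = lapply(insitu, function(x) x),
    exsitu_image_names = lapply(exsitu, function(x) if (is.na(x)) character() else x),
    physical_sample = physical,
    image_credits = paste0("(c) ", institution),
    identified_by = sample(GEN_IDENTIFIERS, n_img, replace = TRUE),
    date_identified = ifelse(has_date_ident,
                             ifelse(date_only, ident_date, ident_datetime),
                             NA_character_),
    identification_remarks = ifelse(stats::runif(n_img) < 0.3,
                                    "identification discussed within the curation team",
                                    NA_character_),
    identification_verification_status = as.integer(status),
    type_status = NA_character_,
    raw_image = paste(cruise, station, event_time, sep = "_"),
    locality = regions$locality[region_idx],
    location_id = regions$location_id[region_idx],
    location_remarks = NA_character_,
    decimal_latitude = ifelse(has_coord, round(stats::runif(n_img, 45, 62), 4), NA_real_),
    decimal_longitude = ifelse(has_coord, round(stats::runif(n_img, -35, -5), 4), NA_real_),
    minimum_depth_m = dmin2,
    maximum_depth_m = dmax2,
    institution_id = institution,
    collection_id = paste0(institution, "-CAT"),
    bibliographic_citation = ifelse(stats::runif(n_img) < 0.4,
                                    paste0(institution, " reference catalogue (2018)"),
                                    NA_character_),
    modified = gen_stamp(seq_len(n_img)),
    license = sample(GEN_LICENSES, n_img, replace = TRUE),
    rights_holder = institution,
    access_rights = "free for scientific use, no commercial use",
    previous_identifications = replicate(n_img, character(), simplify = FALSE),
    catalog_number = ifelse(physical & stats::runif(n_img) < 0.6,
                            sprintf("NHMUK-%06d", sample(1:999999, n_img)),
                            NA_character_),
    associated_sequences = ifelse(physical & stats::runif(n_img) < 0.3,
                                  sprintf("MK%06d", sample(1:999999, n_img)),
                                  NA_character_),
    habitat = sample(GEN_HABITATS, n_img, replace = TRUE),
    substrate_type = substrate,
    size_cm = ifelse(stats::runif(n_img) < 0.5,
                     round(stats::runif(n_img, 0.5, 80), 1), NA_real_),
    substrate_method = ifelse(has_substrate, "Wentworth", NA_character_),
    project_name = sample(GEN_PROJECTS, n_img, replace = TRUE),
    external_link = NA_character_
  )
  # iconic image: best example among the OTU's own files
  for (i in seq_len(n_otus)) {
    rows <- which(images$otu == otu_ids[i])
    files <- unlist(images$insitu_image_names[rows])
    otu$iconic_image[[i]] <- resample(files, 1)
  }
  source_label <- resample(GEN_INSTITUTIONS, 1)
  if (!is.na(image_dir)) {
    materialize_placeholder_images(images, image_dir)
  }
  new_catalogue(otu, images, image_dir = image_dir,
                source_label = source_label, mode = "canonical")
}

# A valid 1x1 grey PNG built from first principles (signature, IHDR, IDAT
# with a zlib-deflated filtered scanline, IEND); placeholder imagery for
# file-existence checks without binary fixtures in the repository.
minimal_png_bytes <- function() {
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(int_be(length(data), 4), body, int_be(crc32(body), 4))
  }
  int_be <- function(value, bytes) rev(int_le(value, bytes))
  ihdr <- c(int_be(1, 4), int_be(1, 4), as.raw(c(8, 0, 0, 0, 0)))  # 8-bit greyscale
  scanline <- as.raw(c(0, 128))  # filter 0, one mid-grey pixel
  idat <- memCompress(scanline, type = "gzip")  # zlib container
  c(
    as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
    chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw())
  )
}

materialize_placeholder_images <- function(images, image_dir) {
  dir.create(image_dir, showWarnings = FALSE, recursive = TRUE)
  bytes <- minimal_png_bytes()
  files <- unique(c(unlist(images$insitu_image_names), unlist(images$exsitu_image_names)))
  for (f in files) {
    writeBin(bytes, file.path(image_dir, f))
  }
  invisible(files)
}

#' Strip a catalogue down to stage-1 transfer form
#'
#' Removes everything a submitting group need not provide — GUIDs,
#' autopopulated taxonomy fields, `CombinedNameID` and `modified` stamps —
#' leaving a transfer-mode catalogue as it would arrive from a data
#' submission.
#'
#' @param cat A catalogue.
#' @return A transfer-mode catalogue.
#' @export
as_transfer <- function(cat) {
  stopifnot(is_catalogue(cat))
  otu <- cat$otu
  images <- cat$images
  otu$number <- NA_character_
  otu$scientific_name <- NA_character_
  otu$scientific_name_authorship <- NA_character_
  otu$taxon_rank <- NA_character_
  otu$combined_name_id <- NA_character_
  images$number <- NA_character_
  images$modified <- NA_character_
  new_catalogue(otu, images, image_dir = cat$image_dir,
                source_label = cat$source_label, mode = "transfer")
}

injectable_rules <- function() {
  c("DEPTH_ORDER", "DEPTH_POSITIVE", "VSTATUS_RANGE", "STATUS3_NOSAMPLE",
    "COORD_RANGE", "SIZE_POSITIVE", "SUBSTRATE_METHOD", "REQ_FIELD",
    "XREF_OTU", "REGION_MISS", "LOCALITY_MISMATCH", "FILE_MISSING",
    "LSID_FORMAT", "TAXON_MISS", "ICONIC_MISSING")
}

OTU_TABLE_RULES <- c("LSID_FORMAT", "TAXON_MISS", "ICONIC_MISSING")

#' Inject labelled violations into a clean catalogue
#'
#' Applies exactly the requested corruptions, each at a distinct record so
#' the ground truth is unambiguous, and returns the expected issue list.
#' The validator's error multiset on the corrupted catalogue equals the
#' returned ground truth: this is the test oracle for the validation
#' module.
#'
#' Supported rule codes: `r paste(injectable_rules(), collapse = ", ")`.
#' (`EXSITU_ALONE` is deliberately not injectable: removing the in-situ
#' image necessarily also violates the required-field rule, which would
#' make the ground truth ambiguous.)
#'
#' @param cat A clean canonical catalogue.
#' @param violations Named integer vector, rule code -> count, e.g.
#'   `c(DEPTH_ORDER = 2, XREF_OTU = 1)`.
#' @param seed Seed for the choice of corrupted records.
#' @return List with `catalogue` (corrupted copy) and `ground_truth`
#'   (tibble `rule_code`, `table`, `record_ref`).
#' @export
inject_violations <- function(cat, violations, seed = 1L) {
  stopifnot(is_catalogue(cat))
  if (!length(violations)) {
    return(list(catalogue = cat, ground_truth = tibble::tibble(
      rule_code = character(), table = character(), record_ref = character()
    )))
  }
  bad <- setdiff(names(violations), injectable_rules())
  if (length(bad)) {
    stop("cannot inject rule code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  rules <- rep(names(violations), times = as.integer(violations))
  img_rules <- rules[!(rules %in% OTU_TABLE_RULES)]
  otu_rules <- rules[rules %in% OTU_TABLE_RULES]
  if (length(img_rules) > nrow(cat$images)) {
    stop("more image-table violations requested than image records available", call. = FALSE)
  }
  if (length(otu_rules) > nrow(cat$otu)) {
    stop("more OTU-table violations requested than OTU records available", call. = FALSE)
  }
  img_rows <- sample.int(nrow(cat$images), length(img_rules))
  otu_rows <- sample.int(nrow(cat$otu), length(otu_rules))
  gt <- list()
  for (k in seq_along(img_rules)) {
    i <- img_rows[k]
    rule <- img_rules[k]
    ref <- cat$images$number[i]
    switch(rule,
      DEPTH_ORDER = {
        cat$images$minimum_depth_m[i] <- cat$images$maximum_depth_m[i] + 100
      },
      DEPTH_POSITIVE = {
        cat$images$minimum_depth_m[i] <- -abs(cat$images$minimum_depth_m[i])
      },
      VSTATUS_RANGE = {
        cat$images$identification_verification_status[i] <- 4L
      },
      STATUS3_NOSAMPLE = {
        cat$images$identification_verification_status[i] <- 3L
        cat$images$physical_sample[i] <- FALSE
      },
      COORD_RANGE = {
        cat$images$decimal_latitude[i] <- 135.5
      },
      SIZE_POSITIVE = {
        cat$images$size_cm[i] <- -5
      },
      SUBSTRATE_METHOD = {
        cat$images$substrate_method[i] <- "Udden"
      },
      REQ_FIELD = {
        cat$images$identified_by[i] <- NA_character_
      },
      XREF_OTU = {
        old_otu <- cat$images$otu[i]
        cat$images$otu[i] <- "OTU_GHOST"
        # keep the donor OTU's iconic image covered by its remaining rows
        j <- which(cat$otu$otu == old_otu)
        rows <- which(cat$images$otu == old_otu)
        files <- as.character(unique(c(unlist(cat$images$insitu_image_names[rows]),
                                       unlist(cat$images$exsitu_image_names[rows]))))
        cat$otu$iconic_image[j] <- list(intersect(cat$otu$iconic_image[[j]], files))
      },
      REGION_MISS = {
        cat$images$location_id[i] <- "MRGID:0"
      },
      LOCALITY_MISMATCH = {
        cat$images$locality[i] <- paste(cat$images$locality[i], "Shoal")
      },
      FILE_MISSING = {
        cat$images$insitu_image_names[[i]] <-
          c(cat$images$insitu_image_names[[i]], sprintf("GHOST%04d.jpg", i))
      },
      stop("unhandled rule: ", rule)
    )
    gt[[length(gt) + 1]] <- tibble::tibble(rule_code = rule, table = "image", record_ref = ref)
  }
  for (k in seq_along(otu_rules)) {
    i <- otu_rows[k]
    rule <- otu_rules[k]
    ref <- cat$otu$number[i]
    switch(rule,
      LSID_FORMAT = {
        cat$otu$scientific_name_id[i] <- as.character(parse_lsid(cat$otu$scientific_name_id[i]))
      },
      TAXON_MISS = {
        cat$otu$scientific_name_id[i] <- make_lsid(99999999L)
      },
      ICONIC_MISSING = {
        cat$otu$iconic_image[[i]] <- c(cat$otu$iconic_image[[i]], "GHOST_ICON.jpg")
      },
      stop("unhandled rule: ", rule)
    )
    gt[[length(gt) + 1]] <- tibble::tibble(rule_code = rule, table = "otu", record_ref = ref)
  }
  list(catalogue = cat, ground_truth = dplyr::bind_rows(gt))
}
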
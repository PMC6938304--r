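# Field dictionaries for the two-table catalogue format.
#
# Each dictionary row ties an internal (snake_case) column name to the exact
# CSV header of the published format, its requirement status, its Darwin Core
# class, and the Darwin Core term it maps onto (NA where no mapping exists).
# Column order is table order; emitted CSV headers follow it exactly.

otu_field_defs <- function() {
  tibble::tribble(
    ~name,                        ~header,                    ~status,        ~dwc_class,       ~dwc_term,                  ~type,
    "number",                     "Number",                   "guid",         NA,               NA,                         "character",
    "otu",                        "OTU",                      "required",     NA,               NA,                         "character",
    "scientific_name",            "scientificName",           "autopopulate", "Taxon",          "scientificName",           "character",
    "scientific_name_id",         "scientificNameID",         "required",     "Taxon",          "scientificNameID",         "character",
    "scientific_name_authorship", "scientificNameAuthorship", "autopopulate", "Taxon",          "scientificNameAuthorship", "character",
    "taxon_rank",                 "taxonRank",                "autopopulate", "Taxon",          "taxonRank",                "character",
    "morphospecies",              "Morphospecies",            "required",     "Identification", "identificationQualifier",  "character",
    "combined_name_id",           "CombinedNameID",           "autopopulate", "Taxon",          "taxonConceptID",           "character",
    "previous_name",              "PreviousName",             "optional",     NA,               NA,                         "list",
    "identification_features",    "IdentificationFeatures",   "optional",     "Taxon",          "taxonRemarks",             "character",
    "iconic_image",               "IconicImage",              "optional",     NA,               NA,                         "list"
  )
}

image_field_defs <- function() {
  tibble::tribble(
    ~name,                                ~header,                             ~status,        ~dwc_class,       ~dwc_term,                           ~type,
    "number",                             "Number",                            "guid",         NA,               NA,                                  "character",
    "otu",                                "OTU",                               "required",     NA,               NA,                                  "character",
    "insitu_image_names",                 "InsituImageName",                   "required",     "Occurrence",     "associatedMedia",                   "list",
    "exsitu_image_names",                 "ExsituImageName",                   "optional",     "Occurrence",     "associatedMedia",                   "list",
    "physical_sample",                    "PhysicalSample",                    "required",     NA,               NA,                                  "logical",
    "image_credits",                      "ImageCredits",                      "required",     "Occurrence",     "associatedReferences",              "character",
    "identified_by",                      "identifiedBy",                      "required",     "Identification", "identifiedBy",                      "character",
    "date_identified",                    "dateIdentified",                    "optional",     "Identification", "dateIdentified",                    "timestamp",
    "identification_remarks",             "identificationRemarks",             "optional",     "Identification", "identificationRemarks",             "character",
    "identification_verification_status", "identificationVerificationStatus",  "required",     "Identification", "identificationVerificationStatus",  "integer",
    "type_status",                        "typeStatus",                        "optional",     "Identification", "typeStatus",                        "character",
    "raw_image",                          "RawImage",                          "required",     "Event",          "eventID",                           "character",
    "locality",                           "locality",                          "required",     "Location",       "locality",                          "character",
    "location_id",                        "locationID",                        "required",     "Location",       "locationID",                        "character",
    "location_remarks",                   "locationRemarks",                   "optional",     "Location",       "locationRemarks",                   "character",
    "decimal_latitude",                   "decimalLatitude",                   "optional",     "Location",       "decimalLatitude",                   "numeric",
    "decimal_longitude",                  "decimalLongitude",                  "optional",     "Location",       "decimalLongitude",                  "numeric",
    "minimum_depth_m",                    "minimumDepthInMeters",              "required",     "Location",       "minimumDepthInMeters",              "numeric",
    "maximum_depth_m",                    "maximumDepthInMeters",              "required",     "Location",       "maximumDepthInMeters",              "numeric",
    "institution_id",                     "institutionID",                     "required",     "Record-level",   "institutionID",                     "character",
    "collection_id",                      "collectionID",                      "optional",     "Record-level",   "collectionID",                      "character",
    "bibliographic_citation",             "bibliographicCitation",             "optional",     "Record-level",   "bibliographicCitation",             "character",
    "modified",                           "modified",                          "autopopulate", "Record-level",   "modified",                          "timestamp",
    "license",                            "dcterms:license",                   "required",     "Record-level",   "license",                           "character",
    "rights_holder",                      "dcterms:rightsHolder",              "required",     "Record-level",   "rightsHolder",                      "character",
    "access_rights",                      "dcterms:accessRights",              "required",     "Record-level",   "accessRights",                      "character",
    "previous_identifications",           "previousIdentifications",           "optional",     "Organism",       "previousIdentifications",           "list",
    "catalog_number",                     "catalogNumber",                     "optional",     "Occurrence",     "catalogNumber",                     "character",
    "associated_sequences",               "associatedSequences",               "optional",     "Occurrence",     "associatedSequences",               "character",
    "habitat",                            "habitat",                           "optional",     "Event",          "habitat",                           "character",
    "substrate_type",                     "SubstrateType",                     "optional",     NA,               NA,                                  "substrate",
    "size_cm",                            "Size",                              "optional",     NA,               NA,                                  "numeric",
    "substrate_method",                   "SubstrateMethod",                   "optional",     NA,               NA,                                  "character",
    "project_name",                       "ProjectName",                       "optional",     NA,               NA,                                  "character",
    "external_link",                      "Link to external database",         "optional",     NA,               NA,                                  "character"
  )
}

#' Field dictionaries of the catalogue transfer format
#'
#' The transfer format consists of two related CSV tables: an OTU table (one
#' row per operational taxonomic unit, 11 fields) and an image table (one row
#' per occurrence/image entry, 35 fields), related through the `OTU` field.
#' These functions return the column dictionary of each table: the exact CSV
#' header, the requirement status of the field (`"required"`, `"optional"`,
#' `"autopopulate"` for fields filled from the taxonomic backbone, or
#' `"guid"` for manager-assigned identifiers), the Darwin Core class the
#' field belongs to and the Darwin Core term it maps onto (`NA` where the
#' format has no Darwin Core equivalent).
#'
#' @return A tibble with columns `name` (internal column name), `header`
#'   (CSV header, exact and case-sensitive), `status`, `dwc_class`,
#'   `dwc_term` and `type`.
#' @examples
#' otu_field_dictionary()
#' image_field_dictionary()
#' @export
otu_field_dictionary <- function() otu_field_defs()

#' @rdname otu_field_dictionary
#' @export
image_field_dictionary <- function() image_field_defs()

field_defs <- function(table = c("otu", "image")) {
  switch(match.arg(table), otu = otu_field_defs(), image = image_field_defs())
}

# Columns that may be absent (or empty) in a transfer-mode file: GUIDs and
# everything the canonicalization step fills in.
transfer_optional_statuses <- c("guid", "autopopulate")

# Controlled vocabulary for the substrate classification standard declared in
# SubstrateMethod.
substrate_methods <- c("Folk", "Wentworth", "EUNIS", "Other")
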
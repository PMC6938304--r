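# smartarid

Tools for building, validating, merging and publishing **standardised
morphospecies reference image catalogues** — the working currency of
image-based benthic ecology, where organisms seen on seafloor imagery
cannot be named to species and are tracked instead as operational
taxonomic units (OTUs) anchored to the lowest defensible taxonomic rank.

The package is aimed at the people who make and curate such catalogues:
benthic ecologists annotating ROV/AUV imagery, taxonomists reviewing
identifications, and data managers assembling regional reference guides
from many groups' submissions.

## The standard in brief

A catalogue is two related CSV tables joined on the `OTU` field:

* **OTU table** (11 fields): GUID `Number`, `OTU`, the WoRMS-style
  taxonomic anchor `scientificNameID` (`urn:lsid:marinespecies.org:taxname:<AphiaID>`)
  with `scientificName` / `scientificNameAuthorship` / `taxonRank`
  autopopulated from it, the `Morphospecies` qualifier, the derived
  `CombinedNameID` = `scientificName + " " + Morphospecies`
  (e.g. *Brisingidae msp1*), the identity history `PreviousName`, free-text
  `IdentificationFeatures`, and the `IconicImage`.
* **image table** (35 fields): one row per occurrence/image entry —
  image files (in-situ required; ex-situ only alongside an in-situ image
  of the same individual), identification metadata with the quality score
  `identificationVerificationStatus` (1 = from image only, 2 = image +
  regional specimens, 3 = image + that specific specimen), event id,
  gazetteer-backed location (`locality`/`locationID`, MRGID), depths in
  positive metres, rights (`dcterms:` fields), substrate composition,
  size, and provenance.

On top of the two-table format the package provides: offline taxonomy and
gazetteer stores with the live-service contracts, field autopopulation,
machine-readable validation (exit codes 0/1/2), catalogue merging with
identification provenance, curation edits that only ever grow the
identity history, regional/depth/taxonomic subsetting, and three end
products: a Darwin Core Archive (occurrence core + multimedia extension +
`meta.xml`), an annotation-scheme taxonomic tree for image-annotation
software, and a printable HTML field guide. A deterministic synthetic
generator makes the whole toolchain testable offline.

## Worked example

```r
library(smartarid)

cfg    <- generator_config(seed = 42, n_otus = 6)
stores <- generate_stores(cfg)                                 # taxa + regions
cat1   <- generate_catalogue(cfg, stores$taxa, stores$regions) # canonical catalogue

cat1
#> <catalogue [canonical]> 6 OTUs, 10 image records (source: IMR-BENTHIC)

cat1$otu[1:3, c("otu", "combined_name_id", "taxon_rank")]
#> # A tibble: 3 × 3
#>   otu     combined_name_id       taxon_rank
#>   <chr>   <chr>                  <chr>
#> 1 OTU_001 Hydrodoris msp1        Phylum
#> 2 OTU_002 Nemapecten msp1        Order
#> 3 OTU_003 Bathycalyx lobate msp1 Family

# a clean catalogue validates with no issues at all
summarize_issues(validate_catalogue(cat1, stores$taxa, stores$regions))
#> # A tibble: 0 × 3

# corrupt two records and the validator pinpoints exactly those rules
inj <- inject_violations(cat1, c(DEPTH_ORDER = 1, STATUS3_NOSAMPLE = 1), seed = 1)
validate_catalogue(inj$catalogue, stores$taxa, stores$regions)[, c("severity", "rule_code", "field")]
#> # A tibble: 2 × 3
#>   severity rule_code        field
#> 1 error    DEPTH_ORDER      minimumDepthInMeters
#> 2 error    STATUS3_NOSAMPLE identificationVerificationStatus

# re-identify an OTU: the old combined name is kept as history
renamed <- rename_otu(cat1, "OTU_001", stores$taxa$lsid[6], "msp4", stores$taxa)
renamed$otu$combined_name_id[1]   #> "Spongigorgo msp4"
renamed$otu$previous_name[[1]]    #> "Hydrodoris msp1"

# identification-quality bookkeeping
s <- catalogue_stats(cat1, stores$taxa)
s$status_histogram   #>  1  2  3
                     #>  2  5  3
s$frac_otus_status3  #> 0.5  — half the OTUs have a specimen-verified image
```

The status histogram counts image records per quality score;
`frac_otus_status3` is the share of OTUs with at least one
specimen-verified (status 3) image — the number a curation programme
tries to raise over time. Exporters follow the same pattern:
`export_dwca(cat1, "out")`, `export_annotation_tree(cat1, stores$taxa,
"out/tree.txt")`, `build_field_guide(cat1, stores$taxa, "out/guide")`.

A command-line interface covers the same workflow
(`inst/exec/smartarid`): `generate`, `validate`, `canonicalize`,
`merge`, `rename-otu`, `reassign-image`, `set-status`, `subset`,
`export {dwca|tree|guide}`, `stats`.

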
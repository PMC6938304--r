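---
title: "Standardised morphospecies reference image catalogues: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardised morphospecies reference image catalogues: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartarid)
```

## The problem this package addresses

Benthic ecologists working with seafloor video and stills usually cannot
name what they see: the characters that separate many deep-sea taxa
(sponge spicules, anemone mesenteries, holothurian ossicles) are invisible
in imagery. The working solution in the field is the *morphospecies
reference image catalogue*: each visually distinct form gets an
operational taxonomic unit (OTU) number, an anchor to the lowest taxonomic
rank that can honestly be assigned, and a set of reference images. The
trouble is that every group builds these catalogues in its own format, so
observations cannot be compared or pooled, and identification quality is
rarely recorded.

`smartarid` implements a transfer and database standard for such
catalogues: two related CSV tables, controlled vocabularies, links to the
marine taxonomic backbone (AphiaID/LSID) and gazetteer (MRGID), a
validation suite, a merge procedure with identification provenance, and
exporters for the three end products practitioners actually ask for — a
Darwin Core Archive for interoperability with occurrence databases, a
taxonomic annotation scheme for image-annotation software, and a printable
field guide.

## The data model

A catalogue is a pair of tables related through the `OTU` field:

* the **OTU table** (11 fields) describes each operational taxonomic
  unit: a GUID (`Number`), the catalogue-local `OTU` identifier, the
  taxonomic anchor (`scientificNameID`, an LSID of the form
  `urn:lsid:marinespecies.org:taxname:<AphiaID>`), three fields
  autopopulated from that anchor (`scientificName`,
  `scientificNameAuthorship`, `taxonRank`), the `Morphospecies`
  qualifier (`msp1`, `encrusting msp1`, ...), the derived
  `CombinedNameID` (= scientificName + space + Morphospecies, e.g.
  `Brisingidae msp1`), the identity history `PreviousName`, free-text
  `IdentificationFeatures`, and the `IconicImage` naming the best example
  image;
* the **image table** (35 fields) describes each occurrence/image entry:
  image files (in-situ required, ex-situ optional — an ex-situ image may
  only enter the catalogue alongside an in-situ image of the same
  individual), identification metadata including the
  `identificationVerificationStatus` quality score, event, location
  (gazetteer-backed `locality`/`locationID`, depths in positive metres,
  optional coordinates to accommodate older and sensitive data), rights,
  and a handful of fields with no Darwin Core equivalent (substrate
  composition, size, project, external link).

The quality score is central to the coordination idea: 1 = identified
from the image only; 2 = from the image plus physical specimens from the
same region; 3 = from the image plus that specific physical specimen.
A specimen may exist while the score is still 1 (collected but not yet
identified); once identified, the score is raised. Hence two package
rules: status 3 without `PhysicalSample = Yes` is always an error, and
`set_verification_status()` refuses downgrades unless forced (a forced
downgrade is logged in `identificationRemarks`).

In R, a catalogue is a list of two tibbles plus provenance (`image_dir`,
`source_label`, `mode`). Multi-valued cells are list-columns; the CSV
carrier encodes them with the standard's `" | "` separator. Two modes
exist: `transfer` (stage-1 exchange; GUIDs, autopopulated and optional
columns may be missing) and `canonical` (curated database; all 46 columns
present, GUIDs unique).

## Micro-syntaxes and numerical choices

* **Pipe lists** are canonically `" | "`-separated. The splitter is
  lenient (missing spaces tolerated, empty segments dropped), the writer
  strict — lenient in, strict out.
* **Dates** are strict ISO 8601; date-only values are legal for
  `dateIdentified` because older catalogues rarely recorded time, and
  their precision is preserved so files round-trip byte-exactly.
* **Numbers** use a decimal point only; thousands separators are parse
  errors, not warnings, because silent locale coercion corrupts depths.
* **Substrate cells** encode `class: percent` pairs (`bedrock: 70 |
  pebble: 30`); a bare class with no percentage is legal, and percentages
  are not required to sum to 100 (the standard does not say they must).
* **CSV dialect**: UTF-8, comma-delimited, RFC 4180 quoting. Column-name
  matching is exact and case-sensitive, including `dcterms:` prefixes and
  the verbatim header `Link to external database`.
* **GUIDs** are version-4 UUIDs drawn from R's RNG, so catalogue
  construction is reproducible under `set.seed()`. They are assigned only
  by `canonicalize()`/`merge_catalogues()` — transfer files may omit them.
* The Darwin Core Archive is a standard ZIP written by a small archive
  writer built on `memCompress()` (deflate entries, CRC-32 computed
  table-wise); archives are verified in the tests by re-reading them with
  base R's independent unzip implementation.

## Reference stores

Autopopulation and gazetteer checks run against offline stores with the
same contract as the live services: `taxa.csv` (AphiaID, LSID, name,
authorship, rank, parent link, accepted flag) and `regions.csv`
(locationID, locality, placetype). Lookups are total over the store's
keys; misses are reported, never fabricated, and an LSID resolving to an
unaccepted name is surfaced as a warning (synonymy itself is managed by
the upstream register — this package only reports it). A live-service
adapter could implement the same contract, but the core and the entire
test suite are network-free by design. No provision is made for taxa
absent from the backbone entirely: such records are flagged as
unresolved rather than inventing a placeholder identifier scheme.

## Validation

`validate_catalogue()` is pure — identical inputs give an identical,
stably ordered issue list — and returns machine-readable issues
(severity, rule code, table, record, field, message) rather than
stopping at the first problem. Decisions worth recording:

* Status 3 with no physical sample is an **error**: a score that claims
  "that specific specimen" entails a specimen exists.
* Status 1 with a physical sample is clean — not even a warning; it is
  the normal state while a collected specimen awaits identification.
* Duplicate `CombinedNameID` across distinct OTUs is a **warning**: the
  standard implies uniqueness but never mandates it.
* Absent coordinates are never flagged, in any mode — they are optional
  precisely to accommodate older and commercially sensitive data.
* An OTU with no image rows is a warning (`OTU_EMPTY`), not an error;
  the standard does not state whether it is legal, and curators may
  stage OTUs before images arrive.
* `Morphospecies` stays required even when a full species-level name is
  known; the qualifier (e.g. `msp1`) still distinguishes morphs.

The validator's soundness and completeness are tested against
`inject_violations()`, which applies labelled corruptions at distinct
records and returns the exact expected issue list. Corruptions are kept
non-overlapping so the ground truth is unambiguous; `EXSITU_ALONE` is
deliberately not injectable because removing the in-situ image also
violates the required-field rule.

## Canonicalization, merging and curation

`canonicalize()` turns a transfer catalogue into canonical form (fresh
GUIDs where missing, autopopulation, `modified` stamp) and is idempotent
apart from the stamp. `merge_catalogues()` groups OTU rows across sources
by the key *(scientificNameID, case-folded Morphospecies)* — the standard
gives no matching rule, and exact-key grouping is the conservative
choice; a curator-supplied mapping file overrides it where groups know
their OTUs correspond. Further choices:

* Global identifiers are `OTU_` plus a zero-padded sequence in merge
  order (the OTU number is a reference number; no ordering semantics).
* Same combined name under different LSIDs (a homonym) is **never**
  merged; the groups are listed in the merge report for curators.
* Conflicting `IdentificationFeatures` keep the longest text (most
  information) and report the alternatives, rather than concatenating
  silently.
* A merged OTU keeps the union of its members' iconic images; choosing
  the single best image is a curatorial act this package does not guess.
* Image rows keep their source provenance untouched (`collectionID`,
  `bibliographicCitation`, source label).

The curation edits mirror the workflow the standard anticipates:
`rename_otu()` (old combined name appended to `PreviousName`),
`reassign_image()` (old OTU appended to `previousIdentifications`),
`set_verification_status()`, and `subset_catalogue()` for building local
guides by gazetteer region, by depth-interval *overlap* (a record whose
depth interval intersects the query interval is kept), or by taxonomic
subtree membership.

## End products

* **Darwin Core Archive**: an *occurrence core* — each image record is
  one occurrence row, with its OTU's taxon fields denormalised on — plus
  a multimedia extension (one row per image file; in-situ and ex-situ
  files as separate rows with a type tag, since `associatedMedia` alone
  cannot distinguish them) and a `meta.xml` whose declared indices are
  tested against the actual columns. Fields with no Darwin Core term go
  losslessly into a JSON `dynamicProperties` column. The verification
  status is emitted as the bare digit, with its meaning documented in
  the archive's metadata stub.
* **Annotation tree**: the union of the OTUs' classification paths, each
  OTU attached as a leaf (labelled by combined name) under its lowest
  resolvable taxon; siblings alphabetical, leaves after internal nodes;
  emitted as an indented text outline and as nested JSON. No annotation
  package's native schema is targeted — the JSON is deliberately generic
  for downstream conversion.
* **Field guide**: one page per OTU (combined name, classification,
  iconic image, identification features, best status, depth envelope
  computed only from that OTU's image rows, localities, credits),
  grouped by a chosen rank, as self-contained HTML plus a single-page
  print variant. Output is deterministic (fixed ordering, no timestamps
  in the body); missing image files render as placeholders with a
  warning so guides still build from partial archives.

## The synthetic generator

All tests run offline on `generate_stores()` / `generate_catalogue()`
output. The generator emulates the *structure* of a real submission — a
rooted taxonomy over the seven Linnean ranks, MRGID-style gazetteer
entries with the standard placetypes, morphospecies qualifiers in the
conventional `msp<k>` form with occasional growth-form prefixes, event
identifiers shaped `CruiseNumber_StationNumber_timestamp`, North
Atlantic deep-sea depths (200–2500 m by default) and coordinates, and
quality scores distributed 60/25/15 % over statuses 1/2/3 with status 3
forcing a physical sample. Defaults describe a small single-group
submission (15 OTUs, 1–3 images each, 30 % ex-situ probability, 25 %
physical-sample probability). It does **not** mimic real taxon-name
frequencies, spatial autocorrelation, or imagery content; passing tests
demonstrate conformance of the machinery, not ecological realism.
Placeholder images are valid 1-pixel PNGs built in code, so
file-existence checks run without binary fixtures.

## Problem sizes used in the checks

The property checks use deliberately small catalogues so the full suite
runs in about a minute: 200 seeded catalogues (4 OTUs, 1–2 images each)
for the round-trip law, 500 injection trials (5 OTUs) for validator
precision/recall, 10 random catalogue pairs for the merge algebra, and a
handful of 5–10-OTU catalogues for exporter checks. These sizes were
chosen as the smallest that still exercise every code path (multi-image
OTUs, shared merge keys, all injectable rules); the laws they check are
size-independent.

## Known limitations

* No image-content checks (resolution, blur, crop quality).
* No geometric containment check of coordinates within the named
  gazetteer region (the offline store carries no polygons).
* No fuzzy taxon-name matching; resolution is by LSID only.
* Legacy spreadsheet/Word/iBooks catalogues are out of scope; they need
  a one-off normaliser before entering the transfer format.
* The merge key treats morphospecies qualifiers as opaque case-folded
  strings; `msp1` and `msp.1` are different OTUs unless a curator maps
  them.
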
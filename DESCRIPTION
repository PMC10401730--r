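Package: cohortquery
Title: Harmonization of Clinical Data Dictionaries and Cross-Cohort
    Patient-Count Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for harmonizing data elements across heterogeneous
    clinical study datasets and answering value-level patient-cohort count
    queries over all of them at once. Parses study data dictionaries
    (codebooks) into a uniform model, represents curated variable-to-concept
    mappings and value recoding tables as a five-file catalog, applies unit
    conversion, numeric binning and range-widening harmonization rules,
    compiles the harmonized concepts into an OWL 2 ontology with permissible
    value and range restrictions, and translates concept-level JSON query
    criteria into per-dataset document-database filters executed against an
    in-memory record store with distinct-patient counting. Includes a
    synthetic two-source cohort generator with planted coding
    inconsistencies and ground-truth query answers for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
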
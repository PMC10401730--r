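---
title: "Harmonized cross-cohort patient-count queries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonized cross-cohort patient-count queries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortquery)
```

## The problem

Two cohort studies that measure the same thing rarely encode it the same
way. Four kinds of coding inconsistency recur when codebooks are laid
side by side:

* **categorical recodes** — the same item with different code→meaning
  maps (`1 = Yes / 2 = No` vs `0 = No / 1 = Yes`);
* **unit clashes** — the same measurement in different units (mm³ vs cc);
* **type clashes** — numeric in one source, categorical in the other
  (packs smoked per day);
* **range clashes** — different declared ranges for the same numeric
  item (years of education, 0–36 vs 0–20).

`cohortquery` models the curated resolution of these inconsistencies as
a *catalog* and uses it to answer concept-level cohort-count queries
against the raw per-source data. Curation itself — deciding which
variables correspond — is input, not computation: automated concept
alignment is out of scope by design.

## Dictionary model

A parsed dictionary is a table of data element definitions: source,
variable name, group (form/CRF), descriptor, inferred data type,
canonical code-spec string, units, and (for multi-table sources) the
housing table. The code-spec grammar splits on `;`; a fragment
`a = label` is a coded category, `lo - hi` or `lo..hi` a numeric range,
and a range accompanied by categories makes those categories *sentinel
codes* (e.g. `99 = Unknown`). Two conventions matter:

* a leading `-` always binds to a code (`-4 = Not available` is a
  category, never a malformed range); negative range endpoints are
  printed with `..` so the grammar stays unambiguous;
* a trailing alias equal to the code (`1=Yes(1)`) is stripped, so labels
  from both dictionary styles compare equal during curation.

The type columns of real codebooks do not separate coded categoricals
from true numerics (both are "Numeric"/"N"), so the parsed code spec
decides: categorical iff it enumerates categories and carries no range.
This inference is applied uniformly to both schemas.

## Harmonization rules

**Range widening.** The harmonized range of a numeric concept is the
interval hull of the per-source declared ranges. The motivating cases
are containments (0–20 inside 0–36, keep 0–36); the hull is the unique
monotone extension to partially overlapping ranges, and is commutative,
associative and idempotent, so curation order cannot matter.

**Unit conversion** is a positive factor with a direction, applied to
raw measurements (divide by 1000: mm³ → cc). Applying a rule and its
inverse recovers the input to relative 1e-12 (one division and one
multiplication in double precision).

**Binning** maps a source's numeric measurements onto the other
source's categories via an interval table. The shipped
`packs_per_day_bins()` table is

| interval | code | meaning |
|---|---|---|
| [0, 0] | 0 | no reported cigarette use |
| (0, 0.5) | 1 | 1 cigarette to < 1/2 pack |
| [0.5, 1) | 2 | 1/2 pack to < 1 pack |
| [1, 1.5) | 3 | 1 pack to 1 1/2 packs |
| [1.5, 2] | 4 | 1 1/2 packs to 2 packs |
| (2, 10] | 5 | more than two packs |

The category wording overlaps at 1.5 packs ("1 pack to 1½ packs" vs
"1½ packs to 2 packs"); the table resolves the tie deterministically by
assigning each boundary to the *upper* category, per the wording of the
upper label, with left-closed/right-open intervals elsewhere and the
final bound closed so the table covers the declared 0–10 range exactly.

**Sentinel codes** (8, 9, 99, −4) are labels, not measurements: they are
never unit-converted or binned. At import they are moved to a shadow
field (`<var>__special`) and the numeric field is left absent, so a raw
−4 can never satisfy an interval with a negative lower bound. For a
binned variable the sentinel passes through into the harmonized
categorical column, where it remains selectable as a category.

**When each rule runs.** Unit and bin rules run once at import, storing
the harmonized value (binning as an added column, so the raw measurement
is preserved). Categorical recoding runs at query time, by inverting the
recode table during translation. This split keeps the bulk import cheap
(no per-row map lookups for recoded categoricals) while keeping
measurement-scale data directly filterable by harmonized ranges.

## The five-file catalog

`save_catalog()` writes `concepts.csv`, `variables.csv`, `mappings.csv`,
`permissible_values.csv` and `value_harmonization.csv`. Concept ids are
slugs of the labels. Harmonized categorical domains and numeric
sentinels live in `permissible_values.csv`; unit factors and serialized
bin tables live as columns on `mappings.csv` rows, since a unit or bin
rule is a property of one (concept, source) mapping. Loading
re-validates all referential invariants: every mapping points to an
existing concept and declared variable, at most one variable per
(concept, source), recode maps are functions, and every harmonized value
lies in its concept's domain.

## Ontology

`build_ontology()` compiles the catalog into an OWL 2 model with a fixed
scaffold — a top class, `DataProperty` with `hasCategory` and
`hasRange` beneath it, and `PermissibleValue` — plus one sub-hierarchy
class per concept category, one class per concept (so every concept
class sits exactly two edges below the top class), and one
permissible-value class per distinct category label. Each categorical
concept class carries one existential (`some`) `hasCategory` restriction
per permissible value; each numeric concept class carries exactly one
`hasRange` restriction, encoded as an `xsd:decimal` datatype restricted
by `minInclusive`/`maxInclusive`.

`class_count()` counts classes of *all* kinds, scaffold included; the
counting rule is explicit because a class total is only comparable
between ontologies under a stated scaffold convention. Serialization is
RDF/XML with a fixed base IRI and alphabetical ordering, so equal
catalogs produce byte-identical files. No reasoning is performed: the
ontology is a knowledge artifact for browsing and for driving query-term
selection, and nothing downstream depends on inference.

## Query semantics

Criteria are a conjunction of terms over one or more datasets.
Translation resolves each concept to the dataset's raw variable,
rewrites selected harmonized codes to raw codes via the inverse recode
map, and passes numeric ranges through unchanged (harmonization already
happened at import). The rendered statement is the document-database
distinct-on-patient-id template with the dataset tag first and one
predicate per term in criteria order.

Three semantic decisions deserve emphasis:

* **Same-record conjunction.** A patient qualifies if *one* record
  satisfies all predicates simultaneously. This is what a single
  `distinct(id, {filter})` statement computes; per-term any-visit
  semantics would require an intersection of separate queries and is
  deliberately not what this engine implements.
* **Multi-table sources.** Each table of a multi-table source imports
  row-wise into the one collection; no cross-table join is attempted. A
  conjunction across variables housed in different tables therefore
  matches no record — no single record carries both fields. This is a
  documented limitation of the one-collection design, and the synthetic
  ground truth models it explicitly.
* **Unreachable codes.** Selecting a harmonized code with no raw
  preimage in a dataset whose recode map exists raises a value-mapping
  error rather than silently matching nothing: an incomplete preimage
  usually signals a curation gap, and a hard error surfaces it. A
  dataset in which a concept is entirely unmapped is instead excluded
  from that query with a notice.

Term summaries use counts per harmonized category for categorical
concepts and the five-number summary for numeric ones. Quartiles follow
the Tukey hinge convention (`stats::fivenum`): hinges are medians of the
lower/upper halves with the median position included for odd *n*, so
`{1,2,3,4,5}` summarizes to `(1, 2, 3, 4, 5)` — the convention box
plots are drawn with.

## Synthetic cohorts and what the tests show

`generate_cohort()` builds a fully self-contained testbed: a single-file
source ("NACC"-style, ids `N000001…`) and a multi-table source
("ADNI"-style, ids `R0001…`, five tables), with seven planted concepts
covering every harmonization challenge — the six-row banked-CSF recode,
the game-of-skill recode, the mm³/cc unit clash, the packs-per-day type
clash, the education range clash, and two cleanly shared concepts.
Defaults are 2,000 patients per source, 1–4 visits each, and 5%
missingness and 5% sentinel rates per variable.

Distributional choices are deliberately plain: categorical values from
fixed per-category probabilities, numerics uniform over declared ranges,
visit rows repeating each patient's time-invariant values. Patient-id
styles differ by source so cross-dataset identity can never arise and
totals are additive by construction. The generator emulates the
*structural* heterogeneity of real multi-source data, not its
statistics: no disease progression, no correlated biomarkers, no
informative missingness, no within-patient visit-to-visit variation.
Passing tests therefore certify the harmonization and counting
machinery, not any clinical realism.

Correctness is checked by two independent oracles: a closed-form answer
function over the generator's patient-level harmonized attributes, and
a brute-force scan of the raw CSVs that inverts the recode map, converts
units and bins values independently of the engine's import path. The
test suite checks engine ≡ oracle on 200 random criteria at the full
2,000+2,000-patient size (plus monotonicity, duplicate-visit invariance
and total additivity on each), and on 60 criteria at a 150+150-patient
size in the per-module suite; the two oracles are checked against each
other on 40 further criteria.

## Numerical conventions and degenerate inputs

* Codes are always text, preserving signed sentinels like `-4` exactly.
* Numbers print without trailing zeros or scientific notation, so CSV
  and statement round trips are stable.
* An empty criteria term list is the vacuous conjunction: the match-all
  filter per dataset.
* An empty catalog builds a scaffold-only ontology; an empty ontology
  document parses to a model with zero classes.
* Bin tables reject values outside all bins; ranges reject `min > max`;
  a categorical spec requires at least one category and pairwise
  distinct codes.

## Limitations

* Concept mapping is curated input; no string matching or embedding
  alignment is attempted.
* The record store is in-memory; the filter dialect matches a document
  database, and an adapter to a real backend would reuse the rendered
  statements, but none is bundled.
* No cross-table joins within a multi-table source (see above).
* The ontology is structural: no reasoner, no synonym enrichment.
* Counts only — no record-level data release and no cross-dataset
  patient linkage.
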
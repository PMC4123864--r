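---
title: "Publishing biodiversity data as Darwin Core Archives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Publishing biodiversity data as Darwin Core Archives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwca)
```

## The data model

Biodiversity datasets — museum specimen records, field observations, taxon
checklists — are mobilized by converting local tables into a common
vocabulary (Darwin Core) and a common container (the Darwin Core Archive).
An archive is a zip file holding:

* one **core** table of delimited text — either occurrence records or taxon
  (checklist) records;
* zero or more **extension** tables whose rows relate *many-to-one* to core
  records through a `coreid` column, forming a star schema (e.g. several
  multimedia items attached to one specimen record);
* `meta.xml`, a structural descriptor stating, for every file, its rowType,
  text dialect (field and line terminators, quoting, encoding, header
  lines) and the mapping from column indices to Darwin Core term URIs;
* `eml.xml`, the dataset metadata (title, creators, coverage, methods,
  rights) in an EML subset.

`dwca` implements the full publishing lifecycle around this container:
reading local delimited files, mapping their columns to Darwin Core terms,
validating record identifiers and archive integrity, packaging and reading
archives, keeping an immutable version history, computing publication
schedules, and exporting metadata as a data-paper manuscript draft.

## Terms and schemas

Terms are identified by their qualified URI; the simple name is the last
path component, and two terms are equal exactly when their URIs are equal.
A *schema* is an ordered term set for one rowType.  Three schema
definitions are bundled as static XML files — the Occurrence Core, the
Taxon Core and the Simple Multimedia extension — so no network access is
ever needed.  The two cores designate their record-identifier terms
(`occurrenceID`, `taxonID`).  Which Darwin Core terms belong to each
bundled subset is a fixture of this package, transcribed once from the
public core definitions; additional extensions can be loaded from
definition documents in the same resource-registry style with
`parse_extension_definition()`.

```{r}
s <- builtin_schemas()
vapply(s, function(x) x$row_type, character(1))
s$occurrence$id_term$simple_name
```

## Mapping local columns to terms

Column mapping follows a deliberately narrow automatic rule: a source
header maps to a term only when the two names are the *same name string*
after case-folding and removal of spaces and underscores.  Nothing fuzzier
is attempted — no edit distance, no synonyms — because a silent mis-mapping
is worse than an unmapped column.  Unmatched headers are reported as
unmapped, and bindings can always be written explicitly in the resource
configuration (including constant values, e.g. a fixed `basisOfRecord`, and
per-column defaults for empty fields).  One source column may feed several
terms; one term may never be bound twice.

The record-identifier column plays a double role: it becomes the structural
id column of the archive and may additionally be bound to the identifier
term.  The writer always emits the id as physical column 0 of each data
file, duplicating the mapped term column when necessary — this keeps the
`coreid` binding of extensions trivial and matches common archive practice.

## Validation and the halt rule

Identifier validation is the publication gate.  Its semantics are:

* an empty or whitespace-only identifier is a `missing_id` error, one per
  row;
* an identifier occurring *k* ≥ 2 times yields one `duplicate_id` error for
  **every** involved row (*k* issues, not *k* − 1), so the report names
  every row a publisher must fix;
* identifier comparison is exact, case-sensitive string equality with no
  trimming — identifiers are opaque, and normalizing them would mask
  exactly the errors the check exists to surface.

Extension rows whose `coreid` matches no core identifier are warnings (the
data are suspect but structurally meaningful); rows with an *empty*
`coreid` are errors.  Row-arity deviations are errors.  A report's verdict
is `halt` exactly when any error-severity issue exists; validation always
collects *all* issues before halting, a usability choice, rather than
stopping at the first.  A halted publication produces no archive and leaves
the version store byte-identical — this is asserted in the test suite by
hashing the store before and after a failing publish.

Controlled-vocabulary checking (`check_vocabulary()`) is resolved as
*flag and suggest, never rewrite*: each distinct non-canonical value is
flagged once with its row count, and a canonical form is suggested when the
value's normalized form (case-folded, punctuation and whitespace stripped)
matches a synonym table.  The package ships a demonstration country
vocabulary — ISO 3166-1 alpha-2 codes with common verbatim spellings of the
United States among its synonyms — which is extensible via plain-text
files.

## Reading and the star join

`read_star_records()` performs the star join by a single pass that builds
an in-memory index of core identifiers and then streams each extension
file; memory therefore grows with the core row count, not with total data
size.  The join is exact string equality.  Orphan extension rows are
dropped from the join (they are validator findings, not reader errors); a
duplicate core identifier makes the join fail loudly, though the halt rule
makes that unreachable for archives this package publishes.  The test suite
checks the join against a brute-force nested-loop oracle on random tables
up to 1000 × 1000 rows.

## Format and numerical choices

* **Writer dialect.** Data files are written tab-delimited, UTF-8,
  LF-terminated, double-quote quoted, with one header line, and *every*
  dialect attribute is stated explicitly in `meta.xml` rather than relying
  on format defaults — bit-exact reproducibility across readers beats
  brevity.  Tab and newline appear in their backslash-escaped forms
  (`\t`, `\n`) in descriptor attributes, never literally.
* **Reader defaults.** When a descriptor omits optional attributes, the
  text-guide defaults apply: comma delimiter, LF line ends, double-quote
  quoting, UTF-8, zero header lines.
* **Dialect sniffing.** The delimiter is chosen from tab, comma, semicolon
  and pipe by the most consistent (and then widest) per-line field count
  over the first 50 lines; a candidate that fails to split lines at all
  (modal arity 1) never beats one that splits them consistently.  Sniffing
  is a convenience: a configuration can always pin the dialect.
* **Ragged rows** pass through the reader unrepaired and are flagged by
  `check_row_arity()`; quality problems are routed to validation, never
  silently fixed.
* **Field fidelity.** Leading/trailing whitespace in data fields is
  preserved; only header names are trimmed.  Fields may contain the
  delimiter and the quote character (quoted, with doubled quotes); embedded
  line terminators are rejected at write time.
* **Zip container.** Archives are written with stored (uncompressed)
  entries and a fixed entry timestamp, so identical inputs produce
  byte-identical archives; entry names are exactly the descriptor
  locations, with no directories inside the zip.  These files are small at
  the package's desk scale, and reproducibility is worth more than
  compression here.

## Versioning, schedules, registration

Published versions are immutable and gapless: version *n* + 1 is created by
republication, never by overwrite, and each version directory holds the
archive, the validation report and a self-contained HTML summary page
(metadata, download link, version table newest first, citation — composed
as "creators (year). title. version." when the metadata carries none).  A
pinned-timestamp mode makes publication byte-deterministic for tests and
reproducible builds.  One version counter serves both data and
metadata-only publications, distinguished by a flag.

Schedules advance the last publication date by the configured interval,
with calendar-month arithmetic clamped to the target month's length
(Jan 31 + 1 month → Feb 28, or Feb 29 in leap years).  **Bi-annually is
interpreted as every six months** (twice a year), not every two years; both
readings exist in publishing-tool lineage, so the choice is isolated in one
function and documented here.  The scheduler only computes due-ness
(`dwca publish --if-due`); there is no daemon — cron-style invocation keeps
the artifact a library plus CLI.

Registration emits a structured document (stable identifier, title,
publishing organization, endpoint of the latest archive) rather than
calling any registry API.  The stable identifier is minted
deterministically from the resource name; when the configuration carries a
registry identifier from a legacy publishing protocol, that identifier is
reused and marked as migrated so the existing registry entry is maintained
rather than duplicated.

## The fixture generator

`generate_fixture()` emulates the *shape* of publisher data: plausible
Darwin Core columns (identifiers, scientific names drawn from a packaged
list, dates, country codes, in-range coordinates) and a multimedia
extension related many-to-one to the core.  Its contract is count
correctness, not ecological realism: errors (duplicate identifiers, missing
identifiers, orphan extension rows, ragged rows, non-canonical country
spellings) are injected *after* clean generation at seeded positions, and
the injection log is returned as ground truth — the validator is tested
against what was constructed, never against a re-derivation by similar
logic.  Each injected duplication overwrites one row's identifier with
another distinct row's, so it contributes exactly two `duplicate_id`
issues under the all-involved-rows rule; extension pointers are drawn only
from identifiers that survive injection, so the only orphans are the
deliberate ones.  The same spec and seed reproduce byte-identical files.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: character-encoding pathologies beyond UTF-8,
multi-line quoted fields, Excel exports, taxonomic or georeferencing
errors, and realistic sampling distributions.  The validator's vocabulary
check is demonstrated on a small country-field fixture carrying the five
classic non-canonical spellings of the United States alongside canonical
`US` rows.

## Problem sizes and limitations

The test suite exercises round trips on 200 random datasets of 1–1000 core
rows with up to three extensions, join-oracle agreement on 50 random tables
up to 1000 × 1000 rows, and validator/ground-truth agreement on 100 random
error specifications; the acceptance script re-runs scaled versions of the
same computations from a fresh seed.  These sizes reflect the package's
target: desk-scale dataset publishing, where whole tables fit comfortably
in memory.  Known limitations: no database connections (delimited text
only), single-file cores, no gzip members or remote archives, no RDF
export, no DOI minting, and no taxonomic-name or georeference cleaning —
the validator flags, it does not fix.
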
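# dwca — Darwin Core Archive publishing toolkit for R

Natural history collections, citizen-science projects and labs hold
biodiversity data in local tables with local column names.  To be
discoverable and reusable, those tables need to be published in the
community standard: records mapped to **Darwin Core** terms and packaged as
a **Darwin Core Archive** — a zip of delimited text files (one core table
of occurrence or taxon records plus many-to-one extension tables forming a
star schema), a structural descriptor (`meta.xml`) and dataset metadata
(`eml.xml` in EML).

`dwca` is a library and command-line toolkit for that publishing
lifecycle, aimed at data managers and biodiversity informaticians:

* **Map** — automatic column-to-term matching where names agree (case and
  `_`/space insensitive), explicit configuration otherwise; constants and
  defaults supported, never fuzzy guessing.
* **Validate** — the publication gate: every record must carry a unique
  `occurrenceID`/`taxonID`.  Missing or duplicate identifiers are errors
  (one issue per involved row) and **halt** publication; orphan extension
  rows, arity mismatches and non-canonical vocabulary values are flagged.
* **Package / read** — write and parse `meta.xml`, build and open archives
  (zip or unzipped directory), and stream **star records**: each core
  record joined with its extension rows by exact `coreid` equality.
* **Version / schedule / register** — immutable, gapless version history
  with summary pages; calendar-aware publication schedules (daily …
  annually, month-end clamped); a registry-registration document that
  maintains legacy registry identifiers on migration.
* **Export** — dataset metadata as an 11-section data-paper manuscript
  draft.
* **Fixtures** — a seeded generator of synthetic occurrence/checklist
  datasets with controlled error injection and by-construction ground
  truth, so the whole pipeline is testable offline.

## Worked example

```r
library(dwca)

# a synthetic survey with one deliberately duplicated occurrenceID
fx <- generate_fixture(
  fixture_spec("occurrence", n_records = 100,
               extension = list(mean_rows = 1),
               errors = list(duplicate_ids = 1), seed = 7),
  "demo_src")

cfg <- list(
  name = "cowbird_survey", core_type = "occurrence",
  core_source = fx$core_path,
  extensions = list(list(source = fx$extension_path)),
  metadata = list(
    title = "Synthetic cowbird survey",
    creators = list(list(name = "Doe", organization = "Example Museum")),
    abstract = "Synthetic demonstration records."))

publish(cfg, "store", pinned_timestamp = "2014-08-06T00:00:00Z")
#> <dwca_validation_report> verdict: halt
#>   duplicate_id: 2
```

The duplicated identifier involves two rows, so the report carries two
`duplicate_id` issues, the verdict is `halt`, and **no archive or version
is created** — the store is untouched.  With clean data
(`errors = list()`), the same call publishes:

```r
v <- publish(cfg, "store", pinned_timestamp = "2014-08-06T00:00:00Z")
v
#> <dwca_published_version> v1 (2014-08-06T00:00:00Z), 100 records

a <- open_archive(v$archive_path)
stars <- read_star_records(a)
length(stars)                      # one star record per core row
#> [1] 100
stars[[1]]$core_values[1:3]
#> http://rs.tdwg.org/dwc/terms/occurrenceID  "occ:000001"
#> http://rs.tdwg.org/dwc/terms/basisOfRecord "PreservedSpecimen"
#> http://rs.tdwg.org/dwc/terms/eventDate     "2003-11-02"
sum(vapply(stars, function(s) length(s$extension_rows[[1]]), integer(1)))
#> [1] 116                          # multimedia rows attached across records
validate_archive(a)
#> <dwca_validation_report> verdict: pass
#>   no issues
```

The version directory (`store/cowbird_survey/v1/`) holds the archive, the
validation report and a self-contained HTML summary page; republication
creates `v2` and leaves `v1` byte-identical.

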
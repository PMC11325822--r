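---
title: "rarecdm: model, catalogs, ETL semantics, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rarecdm: model, catalogs, ETL semantics, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecdm)
```

## The problem and the model

Assembling rare-disease cohorts requires pooling patients across sites, and
that requires a shared intermediate data structure between heterogeneous
hospital sources and a common research database. `rarecdm` implements such
an intermediate model with seven modules — person, case/visit, diagnosis,
procedure, laboratory findings, medication, phenotype, and genotype — and
two ETL routes into a minimal OMOP CDM target. The person module is the hub:
every event module references a `person_id` (and usually a `visit_id`) with
a 0..n cardinality, so an empty event table is always valid and referential
closure (every foreign key resolves inside the bundle) is the model's
central invariant. Identifiers are pseudonymous by contract;
`pseudonymize_id()` provides a salted stable hash for external inputs, so
the same source identifier maps to the same pseudonym under one salt and
records stay linkable without carrying the original key.

The phenotype and genotype modules are the part standard hospital
interchange formats do not cover, and they are what the second ETL route
exists for: symptoms are coded in the Human Phenotype Ontology (HPO,
`HP:#######`), genotypes as named features (mutation-status flags such as
`NPM1` or `CEBPA.bZIP`, and numeric clinical covariates) resolved through a
bundled feature→concept map.

## Catalogs and transcription conventions

All reference data ships as versioned CSV under `inst/extdata/catalogs/`.
Conventions that are not self-evident from the files:

* **Orpha codes** are stored verbatim as printed in the source table,
  including thousands separators (`ORPHA:525,731`), plus a normalized
  integer (`orpha_norm = 525731`) obtained by stripping non-digits. Many
  diseases have none; those stay missing rather than dropping rows.
* **ICD-10-GM wildcards**: a code ending `".-"` denotes the whole
  three-character category. `match_icd10()` treats it as "any code sharing
  the stem, including the bare stem". All other patterns match only
  exactly.
* **Symptom table merged cells**: in the transcribed symptom table, a row
  with an empty disease list inherits the list of the row above (the
  table's visual layout). The verbatim text is kept in
  `diseases_verbatim`; the machine-readable `disease_keys` column resolves
  the free-text disease mentions to exact disease-catalog names. Mentions
  with no catalog counterpart (e.g. "viral hepatitis D" — the disease list
  has no hepatitis D entry) appear only in the verbatim column.
* **Two endocrine symptom groups** (hyper-/hypothyroidism) are kept
  separate as transcribed; domain-level operations take explicit unions
  (`shared_symptoms(catalog, list("Gastroenterology", "Pneumonology",
  c("Endocrinology: Hyperthyroidism", "Endocrinology: Hypothyroidism")))`).
* **Hematology symptoms**: the transcribed overlap table excludes
  hematology; a one-row group (Fever, `HP:0001945`) is bundled so
  four-domain overlap reports are computable. This mirrors the narrative
  description of AML's primary symptom and is the package's own addition.
* **Narrative vs transcription**: the published narrative claims, e.g.,
  that fever, diarrhea, fatigue, and myalgia are shared by all development
  domains, but the transcribed table does not list fever or myalgia for
  the endocrine groups, nor diarrhea for pneumonology. The computed
  three-domain intersection is therefore `{HP:0012378}` (fatigue) only.
  `symptom_overlap_report()` computes from the transcription and *surfaces*
  each unsupported narrative claim instead of silently correcting either
  side.
* **Criteria**: the bundled inclusion criteria are age ≥ 18 completed years
  at admission, admission *and* discharge within 2015-01-01 … 2022-12-31,
  and ≥ 1 qualifying diagnosis. The endocrinology pattern list adds
  `D35.2` (TSH-oma) and the `E03.-` category so that every disease of the
  domain's catalog can satisfy its own domain criteria; the source's
  criteria table groups TSH-oma under the hyperthyroidism heading even
  though its code is not an `E05` code. Whether "older than 18" excludes
  exact 18-year-olds is not decidable from the source; this package
  implements ≥ 18 ("adult" reading) and makes the bound a parameter.
* **Concept identifiers**: only ids that are public standard OHDSI ids are
  bundled as such (gender 8532/8507, value concepts 9191/9189, and the
  printed CEBPA gene-variant measurement 35948202). Every other id is a
  local placeholder in the reserved ≥ 2,000,000,000 range, flagged
  `placeholder = true`. The 124-feature hematology dictionary is
  **synthetic**: the four CEBPA features are real (printed), the other 90
  binary mutation features use real AML-associated gene/fusion names with
  placeholder ids, and 30 numeric clinical features (blood counts, blast
  percentages, chemistry, one DRG cost weight) carry plausible value
  ranges used by the generator. Users with the real feature dictionary
  drop it in as a replacement `genotype_concept_map.csv`.

## ETL semantics

**Core route** (`run_core_etl()` = `transform_persons_visits()` +
`transform_clinical_events()`): one OMOP `person` row per person record
(birth date split into year/month/day; race/ethnicity kept as source values
with concept id 0), one `visit_occurrence` per visit, then diagnoses →
`condition_occurrence`, procedures → `procedure_occurrence`, laboratory
findings → `measurement` (`value_as_number` + UCUM unit), medications →
`drug_exposure`. Where the routing table lists several candidate OMOP
tables per module, this package always writes the module's `default_table`;
the defaults follow OMOP conventions (conditions to `condition_occurrence`,
laboratory values to `measurement`) rather than the verbatim column order
of the transcribed routing table, whose first-listed tables for procedure
and laboratory are evident transcription artifacts. Codes without a bundled
mini-map entry load with concept id 0 and the source code preserved —
record conservation (`rows_in = rows_mapped + rows_unmapped`, nothing
silently dropped) is a tested invariant.

**Genotype/phenotype route** (`run_genopheno_etl()`): registers the
distinct HPO codes of the input in `SOURCE_TO_CONCEPT_MAP`
(`source_vocabulary_id = "HPO"`, deterministic placeholder target
`2100000000 + numeric(code)`, idempotent re-runs), then maps phenotype
records to `observation` rows (presence/absence in `value_as_concept_id`)
and genotype records to the concept map's target table (default
`measurement`; binary status words to `value_as_concept_id`, numbers to
`value_as_number`). Many-to-one mappings are sound: four CEBPA features
sharing one concept id still produce one row per record. Negative mutation
status emits a row with the negative value concept (rather than no row);
the source leaves this open, and an explicit row preserves record
conservation and distinguishes "tested negative" from "not tested".

**Ordering and atomicity.** The store enforces foreign keys eagerly at
insert, so the contract "core route before genotype/phenotype route" is a
hard gate: `run_genopheno_etl()` verifies every person/visit reference of
both record sets against the store *before* any write and aborts leaving
the store untouched.

**Mapping report.** `success_rate = 100 × mapped / (mapped + unmapped)`.
Rejected records (syntactically invalid code or a value that does not fit
the feature's declared kind) are excluded from the denominator — the rate
measures mappability of well-formed records — but are always reported
alongside. Empty input has rate 100 by convention (vacuous success keeps
the metric total); the zero counts make the convention visible.

## The synthetic generator: what it does and does not emulate

`generate_domain_cohort()` emulates the *structure* of two-hospital
inpatient cohorts: every patient gets one qualifying visit inside the
criteria window at age ≥ 18 (ages uniform 18–90), a diagnosis drawn
uniformly from the domain's disease catalog with the code exactly as
catalogued, symptoms sampled only from catalog entries linked to the
assigned disease (inclusion probability 0.5 per linked symptom,
configurable — the source gives no prevalence data), and small per-domain
laboratory/medication/procedure code lists with uniform values in plausible
ranges. `generate_hematology()` adds the wide validation file: default
1,674 patients × 124 feature columns (both printed sizes; the source also
prints 1,673 in its population table — the generator follows the
ETL-validation sentence and the discrepancy is documented here), binary
mutation features positive with probability 0.2 (configurable), every
patient with diagnosis C92.0 and populated race/ethnicity.

Not emulated: comorbidity structure, realistic lab distributions, multiple
visits per episode, mutation co-occurrence, site effects. A green test
therefore establishes that the *pipeline* maps every record whose code or
feature exists in the catalogs — by construction true of the clean
generator — and that violations (dirty mode, broken ordering) are detected;
it does not establish anything epidemiological. The 100% mapping figure is
reproducible precisely because the package controls both the input and the
concept map; on real data the rate is an empirical outcome.

Determinism: all sampling runs under a locally seeded Mersenne-Twister
(caller RNG state restored), row order is canonical (key-sorted), and the
CSV writers fix number formatting, line endings, and encoding, so equal
seeds give byte-identical bundle and store exports.

## Numerical and degenerate-input choices

* Age is computed in completed calendar years (floor), the standard EHR
  convention; the generator guarantees the age bound via a 366-day/year
  lower bound on the birth offset.
* Dates serialize ISO-8601; unparseable optional fields (e.g. missing
  Orpha codes) become missing values, never dropped rows.
* `n_patients = 0` yields a valid empty bundle and a header-only wide file;
  `n_features` below 5 (the four CEBPA features plus one) or above the
  bundled map size is a value error listing available features.
* Store surrogate keys are assigned in sorted order of the pseudonymous
  text keys; event-row ids are sequential per table. Re-running an ETL on
  the same input into a fresh store reproduces the export byte for byte.
* The in-memory store replaces an embedded SQL engine (none is available
  offline in the target environment); its insert path is the only write
  path, so FK enforcement cannot be bypassed, and the CLI reloads store
  directories by replaying the CSVs through that same path.

## Known limitations

* Core-module concept mapping is an exact-match mini-map; no SNOMED
  cross-walks, dose modelling, or visit-type hierarchies.
* No HGVS parsing, VCF ingestion, or variant normalization — genotype
  features are named flags/covariates, as in the validation use case.
* The OMOP target is a minimal v5.4 column subset (the source names tables,
  not a version); no standard vocabulary tables beyond
  `SOURCE_TO_CONCEPT_MAP`.
* The hematology feature dictionary and the per-domain lab/medication/
  procedure lists are package-synthesized placeholders with correct shape,
  not the sites' real element lists.
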
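# rarecdm

Rare diseases are individually scarce but collectively common, and studying
them at scale means pooling patients across hospitals whose source systems
disagree about everything from diagnosis coding to how a gene mutation is
recorded. `rarecdm` implements a customizable **rare-disease common data
model**: a seven-module record structure (person, case/visit, diagnosis,
procedure, laboratory findings, medication, phenotype, genotype) that sits
between hospital source data and the
[OMOP CDM](https://ohdsi.github.io/CommonDataModel/), the de-facto standard
research database of the OHDSI community. It is aimed at medical informatics
teams building multi-center rare-disease cohorts — in particular across
endocrinology, gastroenterology, pneumonology, and (as a validation domain)
hematology/AML — who need a tested, offline-capable reference implementation
of the model, its reference catalogs, and its ETL into OMOP.

## What it does

* **Bundled reference catalogs** (versioned CSV inside the package, no
  terminology-server access needed): the per-domain disease list with
  ICD-10-GM and Orphanet codes, the overlapping-symptom list with HPO codes
  and symptom–disease links, per-domain cohort inclusion criteria
  (adults, inpatient stays 2015-01-01 … 2022-12-31, qualifying diagnosis),
  the module→OMOP routing table, and a genotype feature→concept map whose
  four CEBPA-derived features (`CEBPA.bZIP`, `CEBPA.bZIP.inframe`,
  `CEBPA.TAD`, `CEBPASTAT`) share the OMOP Genomic concept id **35948202**
  (CEBPA gene variant measurement) — a deliberate many-to-one mapping.
* **Two ETL routes** into a minimal OMOP v5.4 store with eager
  referential-integrity enforcement:
  1. a *core route* for demographics, visits, diagnoses, procedures,
     laboratory findings, and medications;
  2. a *genotype/phenotype route* that first registers HPO codes as source
     codes in `SOURCE_TO_CONCEPT_MAP` (HPO has no released OMOP vocabulary;
     local placeholder ids ≥ 2·10⁹ are used and flagged) and then maps
     phenotype records to `observation` and genotype records to
     `measurement` rows. The core route **must** run first; running the
     second route against a store without persons aborts before writing.
* **A per-record mapping report** with
  `success_rate = 100 × mapped / (mapped + unmapped)` (syntactically
  invalid records are counted separately as `rejected`).
* **A seeded synthetic cohort generator** that emulates two-hospital
  inpatient cohorts per domain, including the wide hematology validation
  dataset: by default **1,674 patients × 124 clinical and gene-mutation
  feature columns**, every column pre-registered in the bundled concept
  map, so the clean dataset maps with 100% success by construction.
* **QA reporting and a CLI**: per-domain patient counts, symptom-overlap
  tables (with narrative-vs-transcription discrepancies surfaced), and the
  verbs `generate`, `validate`, `etl-core`, `etl-genopheno`, `report`,
  `catalog`.

## Worked example

```r
library(rarecdm)

catalog <- load_catalogs()
res <- generate_hematology(n_patients = 100, n_features = 124, seed = 42)

store <- init_store()
run_core_etl(res$bundle, catalog, store)
report <- run_genopheno_etl(res$bundle, catalog, store)
print(report)
#> <mapping_report> 12458 record(s): 12458 mapped, 0 unmapped, 0 rejected; success_rate 100.0%

# every CEBPA-derived feature landed on the shared gene-variant concept:
count_rows(store, "measurement",
           function(df) df$measurement_concept_id == 35948202L)
#> [1] 400   # 4 features x 100 patients

cohort_summary(c(endocrinology = 41559, gastroenterology = 1324,
                 pneumonology = 17141, hematology = 1673))
#> <cohort_summary>
#>             domain n_patients
#> 1    endocrinology      41559
#> 2 gastroenterology       1324
#> 3     pneumonology      17141
#> 4       hematology       1673
#>   total: 61,697
```

The 12,458 records are 100 × 124 melted genotype records plus the cohort's
fever phenotype records; `success_rate 100.0%` says every well-formed record
found a concept mapping. Generating with `dirty_fraction > 0` injects
unmapped features/malformed codes and drives the rate below 100, which the
CLI `report --threshold 100` turns into a nonzero exit code.

Command-line equivalent:

```sh
Rscript -e 'rarecdm::rarecdm_cli()' generate --domain hematology --n 1674 --features 124 --seed 42 --out cohort/
Rscript -e 'rarecdm::rarecdm_cli()' etl-core      --bundle cohort/ --store omop/
Rscript -e 'rarecdm::rarecdm_cli()' etl-genopheno --bundle cohort/ --store omop/
Rscript -e 'rarecdm::rarecdm_cli()' report --store omop/ --threshold 100
```

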
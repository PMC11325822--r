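Package: rarecdm
Title: Customizable Rare-Disease Common Data Model with ETL to OMOP
Version: 0.1.0
Authors@R: person("rarecdm", "maintainers", email = "maintainers@rarecdm.org",
    role = c("aut", "cre"))
Description: A seven-module common data model for rare-disease cohorts
    (person, case/visit, diagnosis, procedure, laboratory findings,
    medication, phenotype, genotype) with bundled reference catalogs of
    diseases (ICD-10-GM, Orpha codes), overlapping symptoms (HPO codes),
    module-to-OMOP routing, and a genotype feature concept map. Provides two
    ETL routes into a minimal OMOP CDM v5.4 target store (a core route for
    demographic and clinical modules and a genotype/phenotype route that
    registers HPO codes in SOURCE_TO_CONCEPT_MAP), per-record mapping
    reports with success rates, a seeded synthetic cohort generator
    including a wide hematology genotype dataset, quality-assurance
    summaries, and a multi-stage command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
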
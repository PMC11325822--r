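test_that("bundled catalogs load with the transcribed content", {
  graves <- subset(cat0$diseases, disease_name == "Graves' disease")
  expect_equal(nrow(graves), 1L)
  expect_equal(graves$icd10gm_code, "E05.0")
  expect_equal(graves$orpha_code, "ORPHA:525,731")
  expect_equal(graves$orpha_norm, 525731L)

  fever <- subset(cat0$symptoms, symptom_name == "Fever" & group == "Gastroenterology")
  expect_equal(fever$hpo_code, "HP:0001945")

  expect_gte(nrow(cat0$diseases), 28L)
  expect_setequal(unique(cat0$diseases$domain),
                  c("endocrinology", "gastroenterology", "pneumonology", "hematology"))

  # every transcribed diagnosis code, exactly as printed
  expect_setequal(unique(cat0$diseases$icd10gm_code),
                  c("E05.9", "E05.0", "E05.8", "E06.1", "D35.2", "E03.-", "E03.1",
                    "E03.2", "E89.0", "E06.3", "E23.0", "D86.-", "B15.0", "B16.0",
                    "B17.1", "B17.2", "E83.1", "E83.0", "E88.0", "C34.-", "A15.-",
                    "J10.0", "C92.0"))

  # the four CEBPA-derived features share the printed concept id
  cebpa <- subset(cat0$genotype_map, grepl("^CEBPA", source_feature))
  expect_setequal(cebpa$source_feature,
                  c("CEBPA.bZIP", "CEBPA.bZIP.inframe", "CEBPA.TAD", "CEBPASTAT"))
  expect_true(all(cebpa$target_concept_id == 35948202L))

  # local ids stay in the reserved range and are flagged
  ph <- cat0$genotype_map[cat0$genotype_map$placeholder, ]
  expect_true(all(ph$target_concept_id >= 2e9))
})

test_that("catalog loading rejects missing and malformed inputs", {
  expect_error(load_catalogs(withr::local_tempdir()), class = "rarecdm_config_error")

  dir <- withr::local_tempdir()
  file.copy(list.files(catalog_dir(), full.names = TRUE), dir)
  d <- read.csv(file.path(dir, "diseases.csv"), colClasses = "character")
  d$icd10gm_code[3] <- "EE05"
  write.csv(d, file.path(dir, "diseases.csv"), row.names = FALSE, na = "")
  err <- tryCatch(load_catalogs(dir), error = identity)
  expect_s3_class(err, "rarecdm_validation_error")
  expect_match(conditionMessage(err), "row 3")
  expect_match(conditionMessage(err), "icd10gm_code")
})

test_that("match_icd10 handles wildcards, exact codes, and bad input", {
  expect_true(match_icd10("E05.-", "E05.8"))
  expect_true(match_icd10("E05.0", "E05.0"))
  expect_false(match_icd10("C34.-", "C92.0"))
  expect_true(match_icd10("E05.-", "E05.-"))  # bare stem matches its own wildcard
  expect_error(match_icd10("5E0.", "E05.0"), class = "rarecdm_value_error")
  expect_error(match_icd10("E05.-", "not-a-code"), class = "rarecdm_value_error")
})

test_that("match_icd10 agrees with the stem oracle on the full catalog cross-product", {
  codes <- unique(c(cat0$diseases$icd10gm_code,
                    unlist(lapply(cat0$criteria$icd10_patterns,
                                  function(s) strsplit(s, ";")[[1]]))))
  for (p in codes) for (cc in codes)
    expect_identical(match_icd10(p, cc), icd10_stem_oracle(p, cc),
                     label = sprintf("match_icd10(%s, %s)", p, cc))
  expect_true(all(match_icd10(codes, codes)))  # reflexivity
})

test_that("shared_symptoms computes intersections over the transcription", {
  gastro <- shared_symptoms(cat0, "Gastroenterology")
  expect_setequal(gastro, unique(subset(cat0$symptoms, group == "Gastroenterology")$hpo_code))

  gp <- shared_symptoms(cat0, c("Gastroenterology", "Pneumonology"))
  expect_true(all(c("HP:0001945", "HP:0012378") %in% gp))

  # three development domains, endocrine groups unioned: fatigue only.
  # (The bundled transcription does not list diarrhea for pneumonology,
  # so the often-quoted four-way narrative set does not materialize.)
  endo <- c("Endocrinology: Hyperthyroidism", "Endocrinology: Hypothyroidism")
  triple <- shared_symptoms(cat0, list("Gastroenterology", "Pneumonology", endo))
  expect_identical(triple, "HP:0012378")

  expect_error(shared_symptoms(cat0, "Cardiology"), class = "rarecdm_value_error")
})

test_that("shared_symptoms is commutative, idempotent, and monotone", {
  groups <- unique(cat0$symptoms$group)
  set.seed(42)
  for (i in 1:10) {
    pick <- sample(groups, sample(2:4, 1))
    expect_setequal(shared_symptoms(cat0, pick), shared_symptoms(cat0, rev(pick)))
    expect_setequal(shared_symptoms(cat0, c(pick, pick[1])),
                    shared_symptoms(cat0, pick))
    wider <- shared_symptoms(cat0, pick[-1])
    expect_true(all(shared_symptoms(cat0, pick) %in% wider))
  }
})

test_that("route_for_module returns the bundled routing", {
  ph <- route_for_module(cat0, "Phenotype")
  expect_setequal(ph$omop_tables, c("observation", "measurement"))
  expect_setequal(ph$vocabularies, c("HPO", "SNOMED", "LOINC"))

  med <- route_for_module(cat0, "Medication")
  expect_setequal(med$omop_tables, c("drug_exposure", "observation"))
  expect_setequal(med$vocabularies, c("RxNorm", "ATC"))
  expect_equal(med$default_table, "drug_exposure")

  per <- route_for_module(cat0, "Person")
  expect_setequal(per$vocabularies, c("SNOMED", "Gender"))

  gt <- route_for_module(cat0, "Genotype")
  expect_setequal(gt$omop_tables, c("observation", "measurement"))
  expect_equal(gt$vocabularies, "OMOP Genomic")
})

test_that("cohort criteria validate their fields", {
  cr <- default_criteria(cat0, "hematology")
  expect_s3_class(cr, "cohort_criteria")
  expect_equal(cr$min_age_years, 18L)
  expect_equal(cr$window_start, as.Date("2015-01-01"))
  expect_equal(cr$window_end, as.Date("2022-12-31"))
  expect_equal(cr$icd10_patterns, "C92.0")
  expect_error(cohort_criteria(18, "2022-01-01", "2015-01-01", "C92.0"),
               class = "rarecdm_value_error")
  expect_error(cohort_criteria(-1, "2015-01-01", "2022-12-31", "C92.0"),
               class = "rarecdm_value_error")
})
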
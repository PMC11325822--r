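test_that("generation is deterministic under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(generate_domain_cohort("gastroenterology", 50, seed = 7, catalog = cat0), d1)
  write_bundle(generate_domain_cohort("gastroenterology", 50, seed = 7, catalog = cat0), d2)
  expect_identical(unname(hash_files(d1)), unname(hash_files(d2)))

  other <- generate_domain_cohort("gastroenterology", 50, seed = 8, catalog = cat0)
  expect_false(identical(generate_domain_cohort("gastroenterology", 50, seed = 7,
                                                catalog = cat0)$person$birth_date,
                         other$person$birth_date))
})

test_that("generated cohorts satisfy their domain's catalog and criteria", {
  for (dom in c("endocrinology", "pneumonology")) {
    b <- generate_domain_cohort(dom, 30, seed = 4, catalog = cat0)
    expect_equal(nrow(validate_bundle(b)), 0L)
    codes <- cat0$diseases$icd10gm_code[cat0$diseases$domain == dom]
    expect_true(all(b$diagnosis$icd10gm_code %in% codes))
    cr <- default_criteria(cat0, dom)
    # every diagnosis code matches some criteria pattern
    hit <- vapply(b$diagnosis$icd10gm_code, function(cc)
      any(vapply(cr$icd10_patterns, match_icd10, logical(1), code = cc)), logical(1))
    expect_true(all(hit))
    # and the whole cohort survives its own selection
    expect_equal(nrow(select_cohort(b, cr, cat0)$person), nrow(b$person))
  }
})

test_that("symptoms only attach to diseases the catalog links them to", {
  # ascites (HP:0001541) is tied to hepatitis B/C and hereditary liver
  # disease, never to hepatitis A
  hepA_gets_ascites <- FALSE
  for (seed in 1:5) {
    b <- generate_domain_cohort("gastroenterology", 60, seed = seed, catalog = cat0)
    hepA <- b$diagnosis$person_id[b$diagnosis$icd10gm_code == "B15.0"]
    asc <- b$phenotype$person_id[b$phenotype$hpo_code == "HP:0001541"]
    if (length(intersect(hepA, asc))) hepA_gets_ascites <- TRUE
    # positive control: each emitted symptom is linked to the patient's disease
    dz_of <- setNames(b$diagnosis$icd10gm_code, b$diagnosis$person_id)
    expect_true(all(b$phenotype$hpo_code %in% cat0$symptoms$hpo_code))
  }
  expect_false(hepA_gets_ascites)
})

test_that("hematology generator produces the wide validation layout", {
  res <- generate_hematology(n_patients = 12, n_features = 20, seed = 6, catalog = cat0)
  expect_equal(nrow(res$wide), 12L)
  expect_equal(length(res$features), 20L)
  expect_true(all(c("CEBPA.bZIP", "CEBPA.bZIP.inframe", "CEBPA.TAD", "CEBPASTAT")
                  %in% names(res$wide)))
  expect_true(all(res$features %in% cat0$genotype_map$source_feature))
  expect_true(all(res$bundle$diagnosis$icd10gm_code == "C92.0"))
  expect_true(all(!is.na(res$bundle$person$race)))
  expect_equal(nrow(validate_bundle(res$bundle)), 0L)
  expect_equal(nrow(res$bundle$genotype), 12L * 20L)

  expect_error(generate_hematology(n_features = 4, seed = 1, catalog = cat0),
               class = "rarecdm_value_error")
  err <- tryCatch(generate_hematology(n_features = 10000, seed = 1, catalog = cat0),
                  error = identity)
  expect_s3_class(err, "rarecdm_value_error")
  expect_match(conditionMessage(err), "CEBPA.bZIP")  # lists available features

  empty <- generate_hematology(n_patients = 0, n_features = 10, seed = 1, catalog = cat0)
  expect_equal(nrow(empty$wide), 0L)
  expect_equal(length(empty$features), 10L)
  expect_equal(nrow(empty$bundle$person), 0L)
})

test_that("dirty mode injects unmappable records; fraction 0 recovers clean output", {
  clean <- generate_hematology(n_patients = 10, n_features = 15, seed = 5, catalog = cat0)
  clean2 <- generate_hematology(n_patients = 10, n_features = 15, seed = 5,
                                catalog = cat0, dirty_fraction = 0)
  expect_identical(clean$wide, clean2$wide)

  dirty <- generate_hematology(n_patients = 10, n_features = 15, seed = 5,
                               catalog = cat0, dirty_fraction = 0.5)
  expect_true(any(!dirty$features %in% cat0$genotype_map$source_feature))

  db <- generate_domain_cohort("gastroenterology", 30, seed = 5, catalog = cat0,
                               dirty_fraction = 0.4)
  expect_true(any(!grepl("^HP:[0-9]{7}$", db$phenotype$hpo_code)))
})
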
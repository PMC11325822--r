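test_that("validate_bundle flags broken foreign keys, dates, and codes", {
  b <- make_tiny_bundle()
  expect_equal(nrow(validate_bundle(b)), 0L)

  broken <- b
  broken$diagnosis$person_id[1] <- "GHOST"
  rep <- validate_bundle(broken)
  expect_true("FK_PERSON" %in% rep$rule)

  inv <- b
  inv$visit$discharge_date[2] <- inv$visit$admission_date[2] - 1
  rep <- validate_bundle(inv)
  expect_true("DATE_ORDER" %in% rep$rule)
  expect_true("V2" %in% rep$locator)

  bad <- b
  bad$phenotype$hpo_code[1] <- "HP:12"
  expect_true("HPO_SYNTAX" %in% validate_bundle(bad)$rule)

  nomed <- b
  nomed$medication$atc_code <- NA_character_
  expect_true("MED_CODE" %in% validate_bundle(nomed)$rule)
})

test_that("a well-formed synthetic bundle has zero violations", {
  b <- generate_domain_cohort("pneumonology", 10, seed = 5, catalog = cat0)
  # oracle: exhaustive FK scan independent of validate_bundle
  for (m in c("visit", "diagnosis", "laboratory", "medication", "phenotype"))
    expect_true(all(b[[m]]$person_id %in% b$person$person_id), label = m)
  expect_equal(nrow(validate_bundle(b)), 0L)
})

test_that("select_cohort applies age, window, and diagnosis rules", {
  b <- make_tiny_bundle()
  cr <- cohort_criteria(18, "2015-01-01", "2022-12-31",
                        c("E05.-", "B16.0", "C34.-"))
  kept <- select_cohort(b, cr, cat0)
  # P3 is 17 at admission; P4's visit starts 2014-12-31 (outside the window)
  expect_setequal(kept$person$person_id, c("P1", "P2"))
  expect_equal(nrow(validate_bundle(kept)), 0L)
  expect_true(all(kept$laboratory$person_id %in% kept$person$person_id))

  none <- select_cohort(b, cohort_criteria(18, "2015-01-01", "2022-12-31", character(0)), cat0)
  expect_equal(nrow(none$person), 0L)
})

test_that("select_cohort is idempotent and monotone", {
  b <- generate_domain_cohort("gastroenterology", 40, seed = 11, catalog = cat0)
  cr <- default_criteria(cat0, "gastroenterology")
  once <- select_cohort(b, cr, cat0)
  twice <- select_cohort(once, cr, cat0)
  expect_identical(once$person$person_id, twice$person$person_id)

  narrow <- cohort_criteria(60, "2017-01-01", "2019-12-31", cr$icd10_patterns)
  wide <- cohort_criteria(18, "2015-01-01", "2022-12-31", cr$icd10_patterns)
  expect_true(all(select_cohort(b, narrow, cat0)$person$person_id %in%
                    select_cohort(b, wide, cat0)$person$person_id))
})

test_that("bundle serialization round-trips and is byte-deterministic", {
  b <- generate_domain_cohort("endocrinology", 15, seed = 3, catalog = cat0)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b, d1)
  write_bundle(b, d2)
  expect_identical(unname(hash_files(d1)), unname(hash_files(d2)))

  back <- read_bundle(d1, provenance = attr(b, "provenance"))
  expect_equal(canonicalize_bundle(b), back)
})

test_that("schema drift and empty module files behave as contracted", {
  b <- make_tiny_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)

  # extra column -> parse error naming file and column
  gp <- file.path(dir, "genotype.csv")
  g <- read.csv(gp, colClasses = "character")
  g$surprise <- "x"
  write.csv(g, gp, row.names = FALSE, na = "")
  err <- tryCatch(read_bundle(dir), error = identity)
  expect_s3_class(err, "rarecdm_parse_error")
  expect_match(conditionMessage(err), "genotype.csv")
  expect_match(conditionMessage(err), "surprise")

  # header-only genotype file -> zero records, still valid
  writeLines(paste(bundle_schemas()$genotype, collapse = ","), gp)
  back <- read_bundle(dir)
  expect_equal(nrow(back$genotype), 0L)
  expect_equal(nrow(validate_bundle(back)), 0L)

  # a missing module file is a configuration error
  file.remove(gp)
  expect_error(read_bundle(dir), class = "rarecdm_config_error")
})

test_that("pseudonymization is salted, stable, and linkable", {
  a <- pseudonymize_id(c("patient-1", "patient-2", "patient-1"), salt = "s1")
  expect_equal(a[1], a[3])
  expect_false(a[1] == a[2])
  b <- pseudonymize_id("patient-1", salt = "s2")
  expect_false(a[1] == b)
  expect_error(pseudonymize_id("x", salt = ""), class = "rarecdm_value_error")
})
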
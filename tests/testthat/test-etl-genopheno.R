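test_that("register_hpo_codes registers distinct codes idempotently", {
  st <- init_store()
  ph <- data.frame(hpo_code = c("HP:0001945", "HP:0001945", "HP:0012378"))
  expect_equal(register_hpo_codes(ph, st), 2L)
  scm <- fetch_table(st, "source_to_concept_map")
  expect_setequal(scm$source_code, c("HP:0001945", "HP:0012378"))
  expect_true(all(scm$source_vocabulary_id == "HPO"))
  expect_true(all(scm$target_concept_id >= 2e9))

  expect_equal(register_hpo_codes(ph, st), 0L)
  expect_equal(count_rows(st, "source_to_concept_map"), 2L)
  expect_equal(register_hpo_codes(data.frame(hpo_code = character(0)), st), 0L)
})

test_that("phenotypes map to observation rows; malformed codes are rejected", {
  fx <- load_etl_fixture()
  st <- fx$store
  ph <- rbind(fx$bundle$phenotype,
              data.frame(person_id = "P1", visit_id = "V1", hpo_code = "HP:12",
                         observed = TRUE, noted_at = as.Date("2018-05-01")))
  register_hpo_codes(ph, st)
  rep <- transform_phenotypes(ph, cat0, st)
  expect_equal(unname(rep$counts[["mapped"]]), 2L)
  expect_equal(unname(rep$counts[["rejected"]]), 1L)
  expect_equal(rep$records$reason[rep$records$status == "rejected"],
               "malformed HPO code")

  obs <- fetch_table(st, "observation")
  expect_equal(nrow(obs), 2L)  # rejected record wrote no row
  expect_setequal(obs$observation_source_value, c("HP:0001945", "HP:0012378"))
  expect_true(all(obs$observation_concept_id >= 2e9))
  expect_true(all(obs$value_as_concept_id == 9191L))  # observed -> Positive
})

test_that("phenotype load before the core route raises and writes nothing", {
  st <- init_store()
  b <- make_tiny_bundle()
  err <- tryCatch(transform_phenotypes(b$phenotype, cat0, st), error = identity)
  expect_s3_class(err, "rarecdm_integrity_error")
  expect_match(conditionMessage(err), "core")
  expect_equal(count_rows(st, "observation"), 0L)
})

test_that("genotypes map through the concept map, including many-to-one CEBPA", {
  fx <- load_etl_fixture()
  st <- fx$store
  cebpa <- c("CEBPA.bZIP", "CEBPA.bZIP.inframe", "CEBPA.TAD", "CEBPASTAT")
  g <- data.frame(person_id = "P1", visit_id = "V1",
                  feature_name = c(cebpa, "NOT_IN_MAP", "wbc"),
                  value = c("positive", "negative", "positive", "negative", "positive", "12.3"),
                  assayed_at = as.Date("2018-05-01"))
  rep <- transform_genotypes(g, cat0, st)
  expect_equal(unname(rep$counts[["mapped"]]), 5L)
  expect_equal(unname(rep$counts[["unmapped"]]), 1L)
  expect_equal(rep$records$source[rep$records$status == "unmapped"], "NOT_IN_MAP")

  m <- fetch_table(st, "measurement")
  mc <- m[m$measurement_source_value %in% cebpa, ]
  expect_equal(nrow(mc), 4L)                       # one row per record, never collapsed
  expect_true(all(mc$measurement_concept_id == 35948202L))
  expect_setequal(unique(mc$value_as_concept_id), c(9191L, 9189L))

  wbc <- m[m$measurement_source_value == "wbc", ]
  expect_equal(wbc$value_as_number, 12.3)
  expect_true(is.na(wbc$value_as_concept_id))
})

test_that("a numeric feature with a non-numeric value is rejected, not loaded", {
  fx <- load_etl_fixture()
  g <- data.frame(person_id = "P1", visit_id = "V1", feature_name = "wbc",
                  value = "positive", assayed_at = as.Date("2018-05-01"))
  rep <- transform_genotypes(g, cat0, fx$store)
  expect_equal(unname(rep$counts[["rejected"]]), 1L)
  expect_equal(count_rows(fx$store, "measurement",
                          function(df) df$measurement_source_value == "wbc"), 0L)
})

test_that("run_genopheno_etl orchestrates, reports, and stays atomic", {
  fx <- load_etl_fixture()
  rep <- run_genopheno_etl(fx$bundle, cat0, fx$store)
  expect_equal(rep$success_rate, 100)
  expect_equal(sum(rep$counts), nrow(fx$bundle$phenotype) + nrow(fx$bundle$genotype))

  # 99 mapped / 1 unmapped -> 99.0
  b <- make_tiny_bundle()
  feats <- c(rep("NPM1", 99), "NOT_IN_MAP")
  b$genotype <- data.frame(person_id = "P1", visit_id = "V1", feature_name = feats,
                           value = "positive", assayed_at = as.Date("2018-05-01"),
                           stringsAsFactors = FALSE)
  b$phenotype <- b$phenotype[0, ]
  fx2 <- load_etl_fixture(b)
  rep2 <- run_genopheno_etl(b, cat0, fx2$store)
  expect_equal(rep2$success_rate, 99.0)

  # empty input -> vacuous 100 with zero counts
  b0 <- make_tiny_bundle()
  b0$phenotype <- b0$phenotype[0, ]; b0$genotype <- b0$genotype[0, ]
  fx3 <- load_etl_fixture(b0)
  rep3 <- run_genopheno_etl(b0, cat0, fx3$store)
  expect_equal(rep3$success_rate, 100)
  expect_equal(sum(rep3$counts), 0L)

  # before the core route: abort before any write
  st <- init_store()
  expect_error(run_genopheno_etl(make_tiny_bundle(), cat0, st),
               class = "rarecdm_integrity_error")
  expect_equal(count_rows(st, "observation") + count_rows(st, "measurement") +
                 count_rows(st, "source_to_concept_map"), 0L)
})

test_that("atomicity: a dangling genotype FK aborts before phenotypes commit", {
  fx <- load_etl_fixture()
  b <- fx$bundle
  b$genotype <- rbind(b$genotype,
                      data.frame(person_id = "GHOST", visit_id = NA_character_,
                                 feature_name = "NPM1", value = "positive",
                                 assayed_at = as.Date("2018-05-01")))
  before_obs <- count_rows(fx$store, "observation")
  expect_error(run_genopheno_etl(b, cat0, fx$store), class = "rarecdm_integrity_error")
  expect_equal(count_rows(fx$store, "observation"), before_obs)
  expect_equal(count_rows(fx$store, "source_to_concept_map"), 0L)
})

test_that("melted wide files reach the ETL like bundle genotypes", {
  res <- generate_hematology(n_patients = 8, n_features = 10, seed = 21, catalog = cat0)
  g <- melt_genotype_wide(res$wide,
                          visit_lookup = setNames(res$bundle$visit$visit_id,
                                                  res$bundle$visit$person_id))
  expect_equal(nrow(g), 8L * 10L)
  st <- init_store()
  run_core_etl(res$bundle, cat0, st)
  rep <- transform_genotypes(g, cat0, st)
  expect_equal(rep$success_rate, 100)
  expect_equal(nrow(rep$records), nrow(g))
})
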
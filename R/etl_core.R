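## Core ETL route: demographic, case/visit, diagnosis, procedure,
## laboratory, and medication modules are written straight into the
## OMOP-shaped store following the bundled routing table. This route must
## run before the genotype/phenotype route so that every later event row
## finds its person and visit already loaded.

etl_report <- function(rows) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("etl_report", "data.frame")
  df
}

etl_report_row <- function(module, rows_in, rows_mapped, rows_unmapped) {
  data.frame(module = module, rows_in = rows_in, rows_mapped = rows_mapped,
             rows_unmapped = rows_unmapped, stringsAsFactors = FALSE)
}

#' @export
print.etl_report <- function(x, ...) {
  cat("<etl_report>\n")
  print.data.frame(as.data.frame(x))
  invisible(x)
}

## Integer surrogate keys for pseudonymous text ids, assigned in sorted
## order so repeated runs on the same bundle give identical stores.
assign_keys <- function(existing, new_values) {
  new_values <- sort(unique(new_values))
  ids <- seq_along(new_values) + (if (length(existing)) max(existing) else 0L)
  c(existing, setNames(as.integer(ids), new_values))
}

#' Load persons and visits into the store
#'
#' One `person` row per person record (gender mapped through the bundled
#' gender concept mini-map, source value preserved; race/ethnicity carried
#' as source values with concept id 0 when present) and one
#' `visit_occurrence` row per visit record. Pseudonymous text keys receive
#' deterministic integer surrogate keys kept inside the store.
#'
#' @param bundle an `rdcdm_bundle`.
#' @param catalog a `catalog_bundle` (gender concept mini-map).
#' @param store an `omop_store`.
#' @return an `etl_report` with per-module row counts.
#' @export
transform_persons_visits <- function(bundle, catalog, store) {
  stopifnot(inherits(bundle, "rdcdm_bundle"), inherits(store, "omop_store"))
  p <- sort_module(bundle$person, "person")
  vis <- sort_module(bundle$visit, "visit")

  clash <- intersect(p$person_id, names(store$person_key))
  if (length(clash))
    integrity_error(sprintf("transform_persons_visits(): person_id '%s' already loaded", clash[1]))

  store$person_key <- assign_keys(store$person_key, p$person_id)
  store$visit_key <- assign_keys(store$visit_key, vis$visit_id)
  pid <- unname(store$person_key[p$person_id])
  gender_cid <- minimap_lookup(catalog, p$gender, "Gender")
  insert_rows(store, "person", data.frame(
    person_id = pid,
    gender_concept_id = gender_cid,
    year_of_birth = as.integer(format(p$birth_date, "%Y")),
    month_of_birth = as.integer(format(p$birth_date, "%m")),
    day_of_birth = as.integer(format(p$birth_date, "%d")),
    race_concept_id = 0L,
    ethnicity_concept_id = 0L,
    person_source_value = p$person_id,
    gender_source_value = p$gender,
    race_source_value = p$race,
    ethnicity_source_value = p$ethnicity,
    stringsAsFactors = FALSE))

  if (nrow(vis)) {
    insert_rows(store, "visit_occurrence", data.frame(
      visit_occurrence_id = unname(store$visit_key[vis$visit_id]),
      person_id = unname(store$person_key[vis$person_id]),
      visit_concept_id = 0L,
      visit_start_date = vis$admission_date,
      visit_end_date = vis$discharge_date,
      visit_source_value = vis$visit_id,
      stringsAsFactors = FALSE))
  }
  etl_report(list(
    etl_report_row("Person", nrow(p), sum(gender_cid > 0L), sum(gender_cid == 0L)),
    etl_report_row("Case", nrow(vis), nrow(vis), 0L)))
}

resolve_store_keys <- function(store, df, module) {
  pid <- store$person_key[df$person_id]
  if (anyNA(pid))
    integrity_error(sprintf(
      "%s: record references person_id '%s' not yet loaded; run the core person/visit load first",
      module, df$person_id[which(is.na(pid))[1]]))
  vid <- rep(NA_integer_, nrow(df))
  has_visit <- !is.na(df$visit_id) & nzchar(df$visit_id)
  vid[has_visit] <- store$visit_key[df$visit_id[has_visit]]
  if (any(has_visit & is.na(vid)))
    integrity_error(sprintf(
      "%s: record references visit_id '%s' not yet loaded; run the core person/visit load first",
      module, df$visit_id[which(has_visit & is.na(vid))[1]]))
  list(person_id = unname(pid), visit_occurrence_id = unname(vid))
}

#' Load diagnosis, procedure, laboratory, and medication events
#'
#' Diagnoses become `condition_occurrence` rows (ICD-10-GM code preserved in
#' `condition_source_value`; concept id from the bundled mini-map, else 0),
#' procedures become `procedure_occurrence` rows (OPS code as source value),
#' laboratory findings become `measurement` rows (`value_as_number` plus the
#' UCUM unit as `unit_source_value`), and medications become `drug_exposure`
#' rows (ATC, falling back to RxNorm, as source value). Per module,
#' `rows_mapped + rows_unmapped = rows_in`: a record whose code has no
#' concept id still loads with concept id 0 -- nothing is silently dropped.
#'
#' @param bundle an `rdcdm_bundle` whose persons/visits are already loaded.
#' @param catalog a `catalog_bundle`.
#' @param store an `omop_store`.
#' @return an `etl_report` with per-module row counts.
#' @export
transform_clinical_events <- function(bundle, catalog, store) {
  stopifnot(inherits(bundle, "rdcdm_bundle"), inherits(store, "omop_store"))
  rows <- list()

  d <- sort_module(bundle$diagnosis, "diagnosis")
  if (nrow(d)) {
    keys <- resolve_store_keys(store, d, "diagnosis")
    cid <- minimap_lookup(catalog, d$icd10gm_code, "ICD10GM")
    insert_rows(store, "condition_occurrence", data.frame(
      condition_occurrence_id = next_ids(store, "condition_occurrence", nrow(d)),
      person_id = keys$person_id, visit_occurrence_id = keys$visit_occurrence_id,
      condition_concept_id = cid, condition_start_date = d$diagnosis_date,
      condition_source_value = d$icd10gm_code, stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- etl_report_row("Diagnosis", nrow(d),
                                                sum(cid > 0L), sum(cid == 0L))
  } else rows[[length(rows) + 1L]] <- etl_report_row("Diagnosis", 0L, 0L, 0L)

  pr <- sort_module(bundle$procedure, "procedure")
  if (nrow(pr)) {
    keys <- resolve_store_keys(store, pr, "procedure")
    cid <- minimap_lookup(catalog, pr$ops_code, "OPS")
    insert_rows(store, "procedure_occurrence", data.frame(
      procedure_occurrence_id = next_ids(store, "procedure_occurrence", nrow(pr)),
      person_id = keys$person_id, visit_occurrence_id = keys$visit_occurrence_id,
      procedure_concept_id = cid, procedure_date = pr$procedure_date,
      procedure_source_value = pr$ops_code, stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- etl_report_row("Procedure", nrow(pr),
                                                sum(cid > 0L), sum(cid == 0L))
  } else rows[[length(rows) + 1L]] <- etl_report_row("Procedure", 0L, 0L, 0L)

  lab <- sort_module(bundle$laboratory, "laboratory")
  if (nrow(lab)) {
    keys <- resolve_store_keys(store, lab, "laboratory")
    cid <- minimap_lookup(catalog, lab$loinc_code, "LOINC")
    insert_rows(store, "measurement", data.frame(
      measurement_id = next_ids(store, "measurement", nrow(lab)),
      person_id = keys$person_id, visit_occurrence_id = keys$visit_occurrence_id,
      measurement_concept_id = cid, measurement_date = lab$measured_at,
      value_as_number = lab$value, value_as_concept_id = NA_integer_,
      unit_source_value = lab$ucum_unit, measurement_source_value = lab$loinc_code,
      stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- etl_report_row("LaboratoryFindings", nrow(lab),
                                                sum(cid > 0L), sum(cid == 0L))
  } else rows[[length(rows) + 1L]] <- etl_report_row("LaboratoryFindings", 0L, 0L, 0L)

  med <- sort_module(bundle$medication, "medication")
  if (nrow(med)) {
    keys <- resolve_store_keys(store, med, "medication")
    src <- ifelse(!is.na(med$atc_code) & nzchar(med$atc_code),
                  med$atc_code, med$rxnorm_code)
    cid <- minimap_lookup(catalog, src, "ATC")
    insert_rows(store, "drug_exposure", data.frame(
      drug_exposure_id = next_ids(store, "drug_exposure", nrow(med)),
      person_id = keys$person_id, visit_occurrence_id = keys$visit_occurrence_id,
      drug_concept_id = cid, drug_exposure_start_date = med$start_date,
      drug_source_value = src, stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- etl_report_row("Medication", nrow(med),
                                                sum(cid > 0L), sum(cid == 0L))
  } else rows[[length(rows) + 1L]] <- etl_report_row("Medication", 0L, 0L, 0L)

  etl_report(rows)
}

#' Run the full core route (persons/visits, then clinical events)
#'
#' @inheritParams transform_clinical_events
#' @return an `etl_report` covering all six core modules.
#' @export
run_core_etl <- function(bundle, catalog, store) {
  r1 <- transform_persons_visits(bundle, catalog, store)
  r2 <- transform_clinical_events(bundle, catalog, store)
  etl_report(list(r1, r2))
}
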
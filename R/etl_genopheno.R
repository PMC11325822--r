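## Second ETL route: phenotype records (HPO-coded symptoms) and genotype
## records (gene-mutation and numeric clinical features) into observation /
## measurement rows. HPO has no released OMOP vocabulary, so the distinct
## HPO codes of the input are first registered as individual source codes in
## SOURCE_TO_CONCEPT_MAP with local placeholder target ids -- mirroring the
## usual temporary workaround -- and the route refuses to run before the core
## route has loaded persons and visits.

HPO_PLACEHOLDER_BASE <- 2100000000L

hpo_placeholder_id <- function(hpo_code) {
  HPO_PLACEHOLDER_BASE + as.integer(substr(hpo_code, 4L, 10L))
}

new_mapping_report <- function(records) {
  if (is.null(records) || !nrow(records)) {
    records <- data.frame(locator = character(0), source = character(0),
                          target_table = character(0), target_concept_id = integer(0),
                          status = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  }
  counts <- c(mapped = sum(records$status == "mapped"),
              unmapped = sum(records$status == "unmapped"),
              rejected = sum(records$status == "rejected"))
  denom <- counts[["mapped"]] + counts[["unmapped"]]
  ## Vacuously successful when nothing was eligible for mapping: the rate
  ## measures mappability of well-formed records, and rejected (syntactically
  ## invalid) records are excluded from the denominator by design.
  rate <- if (denom == 0L) 100 else 100 * counts[["mapped"]] / denom
  structure(list(records = records, counts = counts, success_rate = rate),
            class = "mapping_report")
}

#' Combine mapping reports
#' @param ... `mapping_report` objects.
#' @return a single merged `mapping_report` (counts and rate recomputed).
#' @export
merge_mapping_reports <- function(...) {
  reps <- list(...)
  new_mapping_report(do.call(rbind, lapply(reps, function(r) r$records)))
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("<mapping_report> %d record(s): %d mapped, %d unmapped, %d rejected; success_rate %.1f%%\n",
              nrow(x$records), x$counts[["mapped"]], x$counts[["unmapped"]],
              x$counts[["rejected"]], x$success_rate))
  invisible(x)
}

#' Register HPO codes as source codes in SOURCE_TO_CONCEPT_MAP
#'
#' One row per distinct, well-formed HPO code in the input, with
#' `source_vocabulary_id = "HPO"` and a deterministic local placeholder
#' target concept id in the reserved >= 2,000,000,000 range. Idempotent:
#' codes already registered are skipped.
#'
#' @param phenotypes data frame of phenotype records (needs `hpo_code`).
#' @param store an `omop_store`.
#' @return invisibly, the number of newly registered codes.
#' @export
register_hpo_codes <- function(phenotypes, store) {
  stopifnot(inherits(store, "omop_store"))
  codes <- sort(unique(phenotypes$hpo_code))
  codes <- codes[is_hpo(codes)]
  scm <- fetch_table(store, "source_to_concept_map")
  have <- scm$source_code[scm$source_vocabulary_id == "HPO"]
  codes <- setdiff(codes, have)
  if (length(codes)) {
    insert_rows(store, "source_to_concept_map", data.frame(
      source_code = codes, source_concept_id = 0L, source_vocabulary_id = "HPO",
      source_code_description = NA_character_,
      target_concept_id = hpo_placeholder_id(codes),
      target_vocabulary_id = "None",
      valid_start_date = as.Date("1970-01-01"),
      valid_end_date = as.Date("2099-12-31"),
      invalid_reason = NA_character_, stringsAsFactors = FALSE))
  }
  invisible(length(codes))
}

scm_lookup_hpo <- function(store, codes) {
  scm <- fetch_table(store, "source_to_concept_map")
  scm <- scm[scm$source_vocabulary_id == "HPO", , drop = FALSE]
  out <- scm$target_concept_id[match(codes, scm$source_code)]
  out[is.na(out)] <- 0L
  out
}

#' Map phenotype records to observation rows
#'
#' Each well-formed phenotype record becomes one `observation` row with the
#' HPO code as `observation_source_value`, the registered placeholder id (or
#' 0) as `observation_concept_id`, and presence/absence encoded in
#' `value_as_concept_id` through the bundled value-concept mini-map. A record
#' is `mapped` iff its code is in the bundled symptom catalog or registered
#' in SOURCE_TO_CONCEPT_MAP; malformed codes are `rejected` and write no row.
#'
#' @param phenotypes data frame of phenotype records.
#' @param catalog a `catalog_bundle`.
#' @param store an `omop_store` already holding the bundle's persons/visits.
#' @return a `mapping_report`.
#' @export
transform_phenotypes <- function(phenotypes, catalog, store) {
  stopifnot(inherits(store, "omop_store"))
  ph <- coerce_module(as.data.frame(phenotypes, stringsAsFactors = FALSE), "phenotype")
  ph <- sort_module(ph, "phenotype")
  n <- nrow(ph)
  if (!n) return(new_mapping_report(NULL))
  loc <- sprintf("phenotype[%d]", seq_len(n))

  valid <- is_hpo(ph$hpo_code)
  keys <- resolve_store_keys(store, ph, "phenotype")  # ordering gate for all records

  cid <- rep(0L, n)
  cid[valid] <- scm_lookup_hpo(store, ph$hpo_code[valid])
  in_catalog <- ph$hpo_code %in% catalog$symptoms$hpo_code
  status <- ifelse(!valid, "rejected",
                   ifelse(in_catalog | cid > 0L, "mapped", "unmapped"))

  keep <- valid
  if (any(keep)) {
    observed <- ph$observed[keep]
    observed[is.na(observed)] <- TRUE
    val_cid <- minimap_lookup(catalog, ifelse(observed, "positive", "negative"),
                              "Meas Value")
    insert_rows(store, "observation", data.frame(
      observation_id = next_ids(store, "observation", sum(keep)),
      person_id = keys$person_id[keep],
      visit_occurrence_id = keys$visit_occurrence_id[keep],
      observation_concept_id = cid[keep],
      observation_date = ph$noted_at[keep],
      value_as_number = NA_real_,
      value_as_concept_id = val_cid,
      observation_source_value = ph$hpo_code[keep],
      stringsAsFactors = FALSE))
  }
  new_mapping_report(data.frame(
    locator = loc, source = ph$hpo_code, target_table = "observation",
    target_concept_id = ifelse(valid, cid, NA_integer_), status = status,
    reason = ifelse(valid, NA_character_, "malformed HPO code"),
    stringsAsFactors = FALSE))
}

#' Map genotype records to measurement/observation rows
#'
#' A record whose `feature_name` has a row in the bundled genotype concept
#' map becomes one row in that row's target table (default `measurement`)
#' with the mapped concept id. Binary mutation status (`positive` /
#' `negative` / `unknown`) is encoded as `value_as_concept_id` through the
#' bundled value-concept mini-map; numeric clinical features go to
#' `value_as_number`. Several features may share one concept id
#' (many-to-one); each record still produces its own row. Unmapped features
#' are reported and write no row; a numeric feature whose value does not
#' parse is rejected.
#'
#' @param genotypes data frame of genotype records.
#' @param catalog a `catalog_bundle`.
#' @param store an `omop_store` already holding the bundle's persons/visits.
#' @return a `mapping_report`.
#' @export
transform_genotypes <- function(genotypes, catalog, store) {
  stopifnot(inherits(store, "omop_store"))
  g <- coerce_module(as.data.frame(genotypes, stringsAsFactors = FALSE), "genotype")
  g <- sort_module(g, "genotype")
  n <- nrow(g)
  if (!n) return(new_mapping_report(NULL))
  loc <- sprintf("genotype[%d]", seq_len(n))

  keys <- resolve_store_keys(store, g, "genotype")

  map <- catalog$genotype_map
  idx <- match(g$feature_name, map$source_feature)
  mappable <- !is.na(idx)
  kind <- map$value_kind[idx]
  target_tb <- map$target_table[idx]
  cid <- map$target_concept_id[idx]

  num_val <- suppressWarnings(as.numeric(g$value))
  is_binary_val <- tolower(g$value) %in% c("positive", "negative", "unknown")
  bad_value <- mappable &
    ((kind == "numeric" & is.na(num_val)) | (kind == "binary" & !is_binary_val))

  status <- ifelse(!mappable, "unmapped", ifelse(bad_value, "rejected", "mapped"))
  reason <- ifelse(status == "unmapped", "feature not in genotype concept map",
                   ifelse(status == "rejected", "value does not fit the feature's value kind",
                          NA_character_))

  for (tb in c("measurement", "observation")) {
    keep <- which(status == "mapped" & target_tb == tb)
    if (!length(keep)) next
    k_kind <- kind[keep]
    v_num <- ifelse(k_kind == "numeric", num_val[keep], NA_real_)
    v_cid <- rep(NA_integer_, length(keep))
    bin <- k_kind == "binary"
    v_cid[bin] <- minimap_lookup(catalog, tolower(g$value[keep][bin]), "Meas Value")
    if (tb == "measurement") {
      insert_rows(store, "measurement", data.frame(
        measurement_id = next_ids(store, "measurement", length(keep)),
        person_id = keys$person_id[keep],
        visit_occurrence_id = keys$visit_occurrence_id[keep],
        measurement_concept_id = cid[keep],
        measurement_date = g$assayed_at[keep],
        value_as_number = v_num, value_as_concept_id = v_cid,
        unit_source_value = NA_character_,
        measurement_source_value = g$feature_name[keep],
        stringsAsFactors = FALSE))
    } else {
      insert_rows(store, "observation", data.frame(
        observation_id = next_ids(store, "observation", length(keep)),
        person_id = keys$person_id[keep],
        visit_occurrence_id = keys$visit_occurrence_id[keep],
        observation_concept_id = cid[keep],
        observation_date = g$assayed_at[keep],
        value_as_number = v_num, value_as_concept_id = v_cid,
        observation_source_value = g$feature_name[keep],
        stringsAsFactors = FALSE))
    }
  }
  new_mapping_report(data.frame(
    locator = loc, source = g$feature_name,
    target_table = ifelse(mappable, target_tb, NA_character_),
    target_concept_id = ifelse(status == "mapped", cid, NA_integer_),
    status = status, reason = reason, stringsAsFactors = FALSE))
}

#' Run the genotype/phenotype route end to end
#'
#' Orchestrates HPO code registration, then the phenotype and genotype
#' transforms, and merges the two mapping reports. The route is atomic with
#' respect to its ordering precondition: all person/visit references of both
#' record sets are checked against the store before anything is written, so
#' a run attempted before the core route leaves the store untouched.
#'
#' @param bundle an `rdcdm_bundle`.
#' @param catalog a `catalog_bundle`.
#' @param store an `omop_store` already loaded by the core route.
#' @return a `mapping_report` over phenotype + genotype records, whose
#'   `success_rate` is `100 * mapped / (mapped + unmapped)`.
#' @export
run_genopheno_etl <- function(bundle, catalog, store) {
  stopifnot(inherits(bundle, "rdcdm_bundle"), inherits(store, "omop_store"))
  if (!count_rows(store, "person"))
    integrity_error("run_genopheno_etl(): store holds no person rows; the core route must run first")
  ## atomicity: verify every FK of both modules before any write
  resolve_store_keys(store, bundle$phenotype, "phenotype")
  resolve_store_keys(store, bundle$genotype, "genotype")
  register_hpo_codes(bundle$phenotype, store)
  rp <- transform_phenotypes(bundle$phenotype, catalog, store)
  rg <- transform_genotypes(bundle$genotype, catalog, store)
  merge_mapping_reports(rp, rg)
}

#' Melt a wide genotype/clinical file into genotype records
#'
#' The validation-style input is one row per patient and one column per
#' feature. Every non-identifier column becomes one genotype record per
#' patient; values are kept verbatim (binary status words or numbers).
#'
#' @param wide data frame with a `person_id` column and feature columns.
#' @param visit_lookup optional named vector mapping person_id to visit_id
#'   (melted records carry that visit); otherwise visit_id is missing.
#' @param assayed_at date stamped on the records (default today is avoided:
#'   callers pass the cohort's visit date for determinism).
#' @return data frame of genotype records.
#' @export
melt_genotype_wide <- function(wide, visit_lookup = NULL, assayed_at = as.Date("2020-01-01")) {
  if (!"person_id" %in% names(wide))
    parse_error("wide genotype file: missing column person_id")
  feats <- setdiff(names(wide), "person_id")
  n <- nrow(wide)
  out <- data.frame(
    person_id = rep(wide$person_id, times = length(feats)),
    visit_id = NA_character_,
    feature_name = rep(feats, each = n),
    value = unlist(lapply(feats, function(f) as.character(wide[[f]])), use.names = FALSE),
    assayed_at = as.Date(assayed_at),
    stringsAsFactors = FALSE)
  if (!is.null(visit_lookup))
    out$visit_id <- unname(visit_lookup[out$person_id])
  out
}
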
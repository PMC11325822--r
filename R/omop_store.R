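## In-memory OMOP-shaped target store. Holds the minimal v5.4 column subset
## of eight tables, enforces primary-key uniqueness and person/visit foreign
## keys eagerly at insert time (the ordering rule "core load before
## genotype/phenotype load" is thereby a hard, testable contract), and
## exports each table as a deterministic CSV. Backed by an environment so
## inserts mutate the store in place, as a database handle would.

OMOP_SCHEMAS <- list(
  person = c("person_id", "gender_concept_id", "year_of_birth", "month_of_birth",
             "day_of_birth", "race_concept_id", "ethnicity_concept_id",
             "person_source_value", "gender_source_value", "race_source_value",
             "ethnicity_source_value"),
  visit_occurrence = c("visit_occurrence_id", "person_id", "visit_concept_id",
                       "visit_start_date", "visit_end_date", "visit_source_value"),
  condition_occurrence = c("condition_occurrence_id", "person_id",
                           "visit_occurrence_id", "condition_concept_id",
                           "condition_start_date", "condition_source_value"),
  procedure_occurrence = c("procedure_occurrence_id", "person_id",
                           "visit_occurrence_id", "procedure_concept_id",
                           "procedure_date", "procedure_source_value"),
  measurement = c("measurement_id", "person_id", "visit_occurrence_id",
                  "measurement_concept_id", "measurement_date",
                  "value_as_number", "value_as_concept_id", "unit_source_value",
                  "measurement_source_value"),
  observation = c("observation_id", "person_id", "visit_occurrence_id",
                  "observation_concept_id", "observation_date",
                  "value_as_number", "value_as_concept_id",
                  "observation_source_value"),
  drug_exposure = c("drug_exposure_id", "person_id", "visit_occurrence_id",
                    "drug_concept_id", "drug_exposure_start_date",
                    "drug_source_value"),
  source_to_concept_map = c("source_code", "source_concept_id",
                            "source_vocabulary_id", "source_code_description",
                            "target_concept_id", "target_vocabulary_id",
                            "valid_start_date", "valid_end_date", "invalid_reason")
)

OMOP_PK <- c(person = "person_id", visit_occurrence = "visit_occurrence_id",
             condition_occurrence = "condition_occurrence_id",
             procedure_occurrence = "procedure_occurrence_id",
             measurement = "measurement_id", observation = "observation_id",
             drug_exposure = "drug_exposure_id")

OMOP_DATE_COLS <- c("visit_start_date", "visit_end_date", "condition_start_date",
                    "procedure_date", "measurement_date", "observation_date",
                    "drug_exposure_start_date", "valid_start_date", "valid_end_date")

OMOP_CHAR_COLS <- c("person_source_value", "gender_source_value",
                    "race_source_value", "ethnicity_source_value",
                    "visit_source_value", "condition_source_value",
                    "procedure_source_value", "unit_source_value",
                    "measurement_source_value", "observation_source_value",
                    "drug_source_value", "source_code", "source_vocabulary_id",
                    "source_code_description", "target_vocabulary_id",
                    "invalid_reason")

empty_omop_table <- function(table) {
  cols <- OMOP_SCHEMAS[[table]]
  df <- as.data.frame(setNames(lapply(cols, function(nm) {
    if (nm %in% OMOP_DATE_COLS) as.Date(character(0))
    else if (nm %in% OMOP_CHAR_COLS) character(0)
    else if (nm == "value_as_number") numeric(0)
    else integer(0)
  }), cols), stringsAsFactors = FALSE)
  df
}

#' Table layouts of the target store
#' @return named list of column names per table (minimal OMOP v5.4 subset).
#' @export
omop_schemas <- function() OMOP_SCHEMAS

#' Initialize an empty OMOP-shaped store
#'
#' Creates all eight tables (`person`, `visit_occurrence`,
#' `condition_occurrence`, `procedure_occurrence`, `measurement`,
#' `observation`, `drug_exposure`, `source_to_concept_map`) empty, in memory.
#' If `path` is given it becomes the default export directory; a non-empty
#' existing directory is refused unless `overwrite = TRUE`.
#'
#' @param path optional export directory.
#' @param overwrite allow re-initializing over a non-empty `path`.
#' @return object of class `omop_store` (environment; passed by reference).
#' @export
init_store <- function(path = NULL, overwrite = FALSE) {
  if (!is.null(path) && dir.exists(path) &&
      length(list.files(path)) && !isTRUE(overwrite))
    rarecdm_error(sprintf("init_store(): '%s' exists and is not empty (use overwrite = TRUE)", path),
                  "rarecdm_io_error")
  store <- new.env(parent = emptyenv())
  store$tables <- new.env(parent = emptyenv())
  for (tb in names(OMOP_SCHEMAS)) assign(tb, empty_omop_table(tb), envir = store$tables)
  store$path <- path
  store$person_key <- integer(0)   # person_source_value -> person_id
  store$visit_key <- integer(0)    # visit_source_value  -> visit_occurrence_id
  store$counters <- setNames(rep(0L, length(OMOP_PK)), names(OMOP_PK))
  class(store) <- "omop_store"
  store
}

#' @export
print.omop_store <- function(x, ...) {
  cat("<omop_store>\n")
  for (tb in names(OMOP_SCHEMAS))
    cat(sprintf("  %-22s %7d row(s)\n", tb, nrow(get(tb, envir = x$tables))))
  invisible(x)
}

store_table <- function(store, table) {
  if (!table %in% names(OMOP_SCHEMAS))
    value_error(sprintf("unknown OMOP table '%s'", table))
  get(table, envir = store$tables)
}

coerce_omop_rows <- function(rows, table) {
  cols <- OMOP_SCHEMAS[[table]]
  extra <- setdiff(names(rows), cols)
  if (length(extra))
    value_error(sprintf("%s: column(s) not in schema: %s", table,
                        paste(extra, collapse = ", ")))
  for (m in setdiff(cols, names(rows))) rows[[m]] <- NA
  rows <- rows[, cols, drop = FALSE]
  for (nm in cols) {
    if (nm %in% OMOP_DATE_COLS) rows[[nm]] <- as.Date(rows[[nm]])
    else if (nm %in% OMOP_CHAR_COLS) rows[[nm]] <- as.character(rows[[nm]])
    else if (nm == "value_as_number") rows[[nm]] <- as.numeric(rows[[nm]])
    else rows[[nm]] <- as.integer(rows[[nm]])
  }
  rownames(rows) <- NULL
  rows
}

#' Insert rows into a store table
#'
#' Enforces, at insert time: primary-key uniqueness, and for event tables
#' that `person_id` resolves to a loaded person row and any non-missing
#' `visit_occurrence_id` to a loaded visit. A violation aborts the whole
#' insert (no partial commit) with an error identifying the offending row.
#'
#' @param store an `omop_store`.
#' @param table table name.
#' @param rows data frame whose columns are a subset of the table schema.
#' @return invisibly, the number of rows inserted.
#' @export
insert_rows <- function(store, table, rows) {
  stopifnot(inherits(store, "omop_store"))
  rows <- coerce_omop_rows(as.data.frame(rows, stringsAsFactors = FALSE), table)
  cur <- store_table(store, table)
  if (table != "source_to_concept_map") {
    pk <- OMOP_PK[[table]]
    ids <- rows[[pk]]
    if (anyNA(ids) || anyDuplicated(ids) || any(ids %in% cur[[pk]]))
      integrity_error(sprintf("insert into %s: duplicate or missing %s (first offending value: %s)",
                              table, pk, ids[which(is.na(ids) | duplicated(ids) | ids %in% cur[[pk]])[1]]))
  } else {
    key <- paste(rows$source_code, rows$source_vocabulary_id, sep = "\x1f")
    cur_key <- paste(cur$source_code, cur$source_vocabulary_id, sep = "\x1f")
    if (anyDuplicated(key) || any(key %in% cur_key))
      integrity_error("insert into source_to_concept_map: duplicate (source_code, source_vocabulary_id)")
  }
  if (table %in% c("visit_occurrence", "condition_occurrence", "procedure_occurrence",
                   "measurement", "observation", "drug_exposure")) {
    persons <- store_table(store, "person")$person_id
    bad <- which(is.na(rows$person_id) | !rows$person_id %in% persons)
    if (length(bad))
      integrity_error(sprintf(
        "insert into %s: row %d references person_id %s not present in person (load persons first)",
        table, bad[1], rows$person_id[bad[1]]))
    if (table != "visit_occurrence") {
      visits <- store_table(store, "visit_occurrence")$visit_occurrence_id
      has_visit <- !is.na(rows$visit_occurrence_id)
      bad <- which(has_visit & !rows$visit_occurrence_id %in% visits)
      if (length(bad))
        integrity_error(sprintf(
          "insert into %s: row %d references visit_occurrence_id %s not present in visit_occurrence (load visits first)",
          table, bad[1], rows$visit_occurrence_id[bad[1]]))
    }
  }
  assign(table, rbind(cur, rows), envir = store$tables)
  invisible(nrow(rows))
}

#' Count rows of a store table
#'
#' @param store an `omop_store`.
#' @param table table name.
#' @param predicate optional function taking the table data frame and
#'   returning a logical vector of rows to count.
#' @return integer count.
#' @export
count_rows <- function(store, table, predicate = NULL) {
  df <- store_table(store, table)
  if (is.null(predicate)) return(nrow(df))
  sum(predicate(df), na.rm = TRUE)
}

#' Fetch a copy of a store table
#' @param store an `omop_store`.
#' @param table table name.
#' @return data frame (copy; mutating it does not touch the store).
#' @export
fetch_table <- function(store, table) store_table(store, table)

next_ids <- function(store, table, n) {
  start <- store$counters[[table]]
  store$counters[[table]] <- start + as.integer(n)
  seq_len(n) + start
}

#' Export the store as one CSV per table
#'
#' Rows are sorted by primary key (the mapping table by its composite key),
#' so identical stores export byte-identical files.
#'
#' @param store an `omop_store`.
#' @param dir target directory; defaults to the path given at [init_store()].
#' @return invisibly, the paths written.
#' @export
export_store <- function(store, dir = store$path) {
  if (is.null(dir)) value_error("export_store(): no directory given and store has no path")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(OMOP_SCHEMAS), function(tb) {
    df <- store_table(store, tb)
    ord <- if (tb == "source_to_concept_map")
      order(df$source_vocabulary_id, df$source_code) else order(df[[OMOP_PK[[tb]]]])
    write_csv_stable(df[ord, , drop = FALSE], file.path(dir, paste0(tb, ".csv")))
  }, character(1))
  invisible(paths)
}
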
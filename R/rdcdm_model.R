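## The seven-module record model: one person table plus case/visit,
## diagnosis, procedure, laboratory, medication, phenotype, and genotype
## event tables, all keyed by pseudonymous person/visit identifiers with a
## 0..n relationship from person to every event table.

BUNDLE_SCHEMAS <- list(
  person     = c("person_id", "gender", "birth_date", "age_at_diagnosis",
                 "postal_code", "race", "ethnicity"),
  visit      = c("visit_id", "person_id", "admission_date", "discharge_date",
                 "visit_kind"),
  diagnosis  = c("person_id", "visit_id", "icd10gm_code", "orpha_code",
                 "diagnosis_date"),
  procedure  = c("person_id", "visit_id", "ops_code", "procedure_date"),
  laboratory = c("person_id", "visit_id", "loinc_code", "value", "ucum_unit",
                 "measured_at"),
  medication = c("person_id", "visit_id", "atc_code", "rxnorm_code",
                 "start_date"),
  phenotype  = c("person_id", "visit_id", "hpo_code", "observed", "noted_at"),
  genotype   = c("person_id", "visit_id", "feature_name", "value", "assayed_at")
)

BUNDLE_DATE_COLS <- list(
  person = "birth_date", visit = c("admission_date", "discharge_date"),
  diagnosis = "diagnosis_date", procedure = "procedure_date",
  laboratory = "measured_at", medication = "start_date",
  phenotype = "noted_at", genotype = "assayed_at"
)

GENDER_LEVELS <- c("female", "male", "other", "unknown")
VISIT_KINDS <- c("inpatient_full", "inpatient_partial")

empty_module <- function(module) {
  cols <- BUNDLE_SCHEMAS[[module]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  for (dc in BUNDLE_DATE_COLS[[module]]) df[[dc]] <- as.Date(character(0))
  if (module == "person") df$age_at_diagnosis <- integer(0)
  if (module == "laboratory") df$value <- numeric(0)
  if (module == "phenotype") df$observed <- logical(0)
  df
}

coerce_module <- function(df, module) {
  cols <- BUNDLE_SCHEMAS[[module]]
  extra <- setdiff(names(df), cols)
  if (length(extra))
    parse_error(sprintf("%s: unknown column(s): %s", module, paste(extra, collapse = ", ")))
  for (m in setdiff(cols, names(df))) df[[m]] <- NA_character_
  df <- df[, cols, drop = FALSE]
  for (nm in cols) {      # empty CSV cells are missing values
    if (is.character(df[[nm]])) df[[nm]][!is.na(df[[nm]]) & df[[nm]] == ""] <- NA
  }
  for (dc in BUNDLE_DATE_COLS[[module]]) df[[dc]] <- as.Date(df[[dc]])
  if (module == "person") df$age_at_diagnosis <- suppressWarnings(as.integer(df$age_at_diagnosis))
  if (module == "laboratory") df$value <- suppressWarnings(as.numeric(df$value))
  if (module == "phenotype") {
    if (is.character(df$observed)) df$observed <- tolower(df$observed) %in% c("true", "1", "yes")
    df$observed <- as.logical(df$observed)
  }
  if (module == "genotype") df$value <- as.character(df$value)
  rownames(df) <- NULL
  df
}

#' Construct a seven-module record bundle
#'
#' Missing modules default to empty tables (the person-to-event
#' relationship is 0..n, so empty event tables are valid). Columns are
#' coerced to canonical types; unknown columns are an error.
#'
#' @param person,visit,diagnosis,procedure,laboratory,medication,phenotype,genotype
#'   data frames following the module schemas (see `bundle_schemas()`).
#' @param provenance named list describing origin, e.g.
#'   `list(domain = "hematology", site = "SITE-A", seed = 42)`.
#' @return object of class `rdcdm_bundle`.
#' @export
rdcdm_bundle <- function(person = NULL, visit = NULL, diagnosis = NULL,
                         procedure = NULL, laboratory = NULL, medication = NULL,
                         phenotype = NULL, genotype = NULL, provenance = list()) {
  modules <- list(person = person, visit = visit, diagnosis = diagnosis,
                  procedure = procedure, laboratory = laboratory,
                  medication = medication, phenotype = phenotype,
                  genotype = genotype)
  out <- lapply(names(modules), function(m) {
    if (is.null(modules[[m]])) empty_module(m) else coerce_module(modules[[m]], m)
  })
  names(out) <- names(modules)
  structure(out, provenance = provenance, class = "rdcdm_bundle")
}

#' Module schemas of the record model
#' @return named list of character vectors (column names per module).
#' @export
bundle_schemas <- function() BUNDLE_SCHEMAS

#' @export
print.rdcdm_bundle <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<rdcdm_bundle>")
  if (!is.null(prov$domain)) cat(sprintf(" domain=%s", prov$domain))
  if (!is.null(prov$seed)) cat(sprintf(" seed=%s", prov$seed))
  cat("\n")
  for (m in names(BUNDLE_SCHEMAS))
    cat(sprintf("  %-10s %6d record(s)\n", m, nrow(x[[m]])))
  invisible(x)
}

violation <- function(rule, table, locator, message) {
  data.frame(rule = rule, table = table, locator = locator, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a bundle against the model invariants
#'
#' Violations are data, not exceptions: the returned report lists one row
#' per violated rule instance (primary-key uniqueness, referential closure of
#' every foreign key, date ordering, code syntax, value constraints). A
#' bundle with zero rows is well formed.
#'
#' @param bundle an `rdcdm_bundle`.
#' @return data frame of class `validation_report` with columns
#'   `rule`, `table`, `locator`, `message`.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "rdcdm_bundle"))
  v <- list()
  p <- bundle$person
  dup <- duplicated(p$person_id)
  if (any(dup))
    v[[length(v) + 1L]] <- violation("PK_PERSON_UNIQUE", "person",
                                     p$person_id[dup], "duplicate person_id")
  if (any(bad <- !is.na(p$age_at_diagnosis) & p$age_at_diagnosis < 0L))
    v[[length(v) + 1L]] <- violation("AGE_NONNEG", "person", p$person_id[bad],
                                     "age_at_diagnosis < 0")
  if (any(bad <- !p$gender %in% GENDER_LEVELS))
    v[[length(v) + 1L]] <- violation("GENDER_ENUM", "person", p$person_id[bad],
                                     "gender outside {female, male, other, unknown}")

  vis <- bundle$visit
  dup <- duplicated(vis$visit_id)
  if (any(dup))
    v[[length(v) + 1L]] <- violation("PK_VISIT_UNIQUE", "visit",
                                     vis$visit_id[dup], "duplicate visit_id")
  if (any(bad <- !vis$person_id %in% p$person_id))
    v[[length(v) + 1L]] <- violation("FK_PERSON", "visit", vis$visit_id[bad],
                                     "person_id does not resolve")
  bad <- !is.na(vis$admission_date) & !is.na(vis$discharge_date) &
    vis$discharge_date < vis$admission_date
  if (any(bad))
    v[[length(v) + 1L]] <- violation("DATE_ORDER", "visit", vis$visit_id[bad],
                                     "discharge_date before admission_date")
  if (any(bad <- !vis$visit_kind %in% VISIT_KINDS))
    v[[length(v) + 1L]] <- violation("VISIT_KIND", "visit", vis$visit_id[bad],
                                     "visit_kind outside {inpatient_full, inpatient_partial}")

  for (m in c("diagnosis", "procedure", "laboratory", "medication",
              "phenotype", "genotype")) {
    df <- bundle[[m]]
    if (!nrow(df)) next
    loc <- sprintf("%s[%d]", m, seq_len(nrow(df)))
    if (any(bad <- !df$person_id %in% p$person_id))
      v[[length(v) + 1L]] <- violation("FK_PERSON", m, loc[bad],
                                       "person_id does not resolve")
    has_visit <- !is.na(df$visit_id) & nzchar(df$visit_id)
    if (any(bad <- has_visit & !df$visit_id %in% vis$visit_id))
      v[[length(v) + 1L]] <- violation("FK_VISIT", m, loc[bad],
                                       "visit_id does not resolve")
  }

  d <- bundle$diagnosis
  if (nrow(d) && any(bad <- !is_icd10gm(d$icd10gm_code)))
    v[[length(v) + 1L]] <- violation("ICD10_SYNTAX", "diagnosis",
                                     sprintf("diagnosis[%d]", which(bad)),
                                     "malformed ICD-10-GM code")
  ph <- bundle$phenotype
  if (nrow(ph) && any(bad <- !is_hpo(ph$hpo_code)))
    v[[length(v) + 1L]] <- violation("HPO_SYNTAX", "phenotype",
                                     sprintf("phenotype[%d]", which(bad)),
                                     "hpo_code does not match HP:#######")
  lab <- bundle$laboratory
  if (nrow(lab)) {
    bad <- !is.na(lab$value) & (is.na(lab$ucum_unit) | !nzchar(lab$ucum_unit))
    if (any(bad))
      v[[length(v) + 1L]] <- violation("LAB_UNIT", "laboratory",
                                       sprintf("laboratory[%d]", which(bad)),
                                       "value present without ucum_unit")
  }
  med <- bundle$medication
  if (nrow(med)) {
    has <- function(x) !is.na(x) & nzchar(x)
    bad <- !(has(med$atc_code) | has(med$rxnorm_code))
    if (any(bad))
      v[[length(v) + 1L]] <- violation("MED_CODE", "medication",
                                       sprintf("medication[%d]", which(bad)),
                                       "neither atc_code nor rxnorm_code present")
  }

  out <- if (length(v)) do.call(rbind, v) else
    violation(character(0), character(0), character(0), character(0))
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) cat("<validation_report> 0 violations\n")
  else {
    cat(sprintf("<validation_report> %d violation(s)\n", nrow(x)))
    print.data.frame(utils::head(as.data.frame(x), 20))
  }
  invisible(x)
}

#' Apply cohort inclusion criteria to a bundle
#'
#' A person is retained iff they have at least one visit whose admission and
#' discharge both fall inside the criteria window and at which they are at
#' least `min_age_years` old (completed years), and at least one diagnosis
#' matching one of the criteria's ICD-10-GM patterns. All records of removed
#' persons are dropped, so the result still satisfies referential closure.
#'
#' @param bundle an `rdcdm_bundle` that validates with zero violations.
#' @param criteria a `cohort_criteria` object.
#' @param catalog a `catalog_bundle` (the code matcher's home; kept explicit
#'   so criteria can be replayed against a modified catalog).
#' @return the filtered `rdcdm_bundle`.
#' @export
select_cohort <- function(bundle, criteria, catalog) {
  stopifnot(inherits(bundle, "rdcdm_bundle"), inherits(criteria, "cohort_criteria"))
  rep <- validate_bundle(bundle)
  if (nrow(rep))
    validation_error(sprintf("select_cohort(): bundle has %d validation violation(s)", nrow(rep)))

  p <- bundle$person; vis <- bundle$visit; d <- bundle$diagnosis
  in_window <- vis$admission_date >= criteria$window_start &
    vis$admission_date <= criteria$window_end &
    vis$discharge_date >= criteria$window_start &
    vis$discharge_date <= criteria$window_end
  birth <- p$birth_date[match(vis$person_id, p$person_id)]
  old_enough <- age_in_years(birth, vis$admission_date) >= criteria$min_age_years
  ok_visit_persons <- unique(vis$person_id[in_window & old_enough])

  ok_dx_persons <- if (nrow(d) && length(criteria$icd10_patterns)) {
    hit <- Reduce(`|`, lapply(criteria$icd10_patterns,
                              function(pt) match_icd10(pt, d$icd10gm_code)))
    unique(d$person_id[hit])
  } else character(0)

  keep <- intersect(ok_visit_persons, ok_dx_persons)
  filter_bundle(bundle, keep)
}

filter_bundle <- function(bundle, person_ids) {
  out <- lapply(names(BUNDLE_SCHEMAS), function(m) {
    df <- bundle[[m]]
    df <- df[df$person_id %in% person_ids, , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(out) <- names(BUNDLE_SCHEMAS)
  structure(out, provenance = attr(bundle, "provenance"), class = "rdcdm_bundle")
}

sort_module <- function(df, module) {
  ord <- switch(module,
    person = order(df$person_id),
    visit = order(df$visit_id),
    do.call(order, unname(as.list(df[, BUNDLE_SCHEMAS[[module]], drop = FALSE]))))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Canonicalize a bundle (deterministic row order)
#'
#' Sorts every module by its primary/foreign keys. Two bundles holding the
#' same records serialize to byte-identical files after canonicalization.
#'
#' @param bundle an `rdcdm_bundle`.
#' @return the sorted bundle.
#' @export
canonicalize_bundle <- function(bundle) {
  out <- lapply(names(BUNDLE_SCHEMAS), function(m) sort_module(bundle[[m]], m))
  names(out) <- names(BUNDLE_SCHEMAS)
  structure(out, provenance = attr(bundle, "provenance"), class = "rdcdm_bundle")
}

#' Write a bundle to a directory of CSV files
#'
#' One UTF-8 comma-delimited file per module (`person.csv`, `visit.csv`,
#' `diagnosis.csv`, `procedure.csv`, `laboratory.csv`, `medication.csv`,
#' `phenotype.csv`, `genotype.csv`), rows in canonical key order, dates
#' ISO-8601. Identical bundles produce byte-identical files.
#'
#' @param bundle an `rdcdm_bundle`.
#' @param dir target directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "rdcdm_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- canonicalize_bundle(bundle)
  paths <- vapply(names(BUNDLE_SCHEMAS), function(m) {
    write_csv_stable(bundle[[m]], file.path(dir, paste0(m, ".csv")))
  }, character(1))
  invisible(paths)
}

#' Read a bundle from a directory of CSV files
#'
#' All eight module files must be present (header-only files are fine).
#' Unknown or missing columns abort with an error naming file and column.
#'
#' @param dir directory written by [write_bundle()] or following the same
#'   layout.
#' @param provenance optional provenance list to attach.
#' @return an `rdcdm_bundle` in canonical row order.
#' @export
read_bundle <- function(dir, provenance = list()) {
  if (!dir.exists(dir)) config_error(sprintf("bundle directory does not exist: %s", dir))
  modules <- lapply(names(BUNDLE_SCHEMAS), function(m) {
    path <- file.path(dir, paste0(m, ".csv"))
    if (!file.exists(path)) config_error(sprintf("missing module file: %s", basename(path)))
    read_csv_strict(path, BUNDLE_SCHEMAS[[m]])
  })
  names(modules) <- names(BUNDLE_SCHEMAS)
  canonicalize_bundle(do.call(rdcdm_bundle, c(modules, list(provenance = provenance))))
}
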
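## Bundled reference catalogs: disease list, overlapping-symptom list with
## HPO codes, module-to-OMOP routing, genotype feature concept map, cohort
## inclusion criteria, and two small code mini-maps. All ship as versioned
## UTF-8 CSV inside the package; nothing is fetched from a terminology server.

CATALOG_FILES <- c(
  diseases     = "diseases.csv",
  symptoms     = "symptoms.csv",
  routes       = "routes.csv",
  genotype_map = "genotype_concept_map.csv",
  criteria     = "criteria.csv"
)

RDCDM_MODULES <- c("Person", "Diagnosis", "Procedure", "LaboratoryFindings",
                   "Medication", "Genotype", "Phenotype")
RDCDM_DOMAINS <- c("endocrinology", "gastroenterology", "pneumonology", "hematology")
OMOP_EVENT_TABLES <- c("person", "visit_occurrence", "condition_occurrence",
                       "procedure_occurrence", "measurement", "observation",
                       "drug_exposure")

#' Default directory of the bundled catalogs
#' @return path to the packaged catalog directory.
#' @export
catalog_dir <- function() {
  system.file("extdata", "catalogs", package = "rarecdm", mustWork = TRUE)
}

#' Load and validate the bundled reference catalogs
#'
#' Reads the disease list (with ICD-10-GM and Orpha codes), the
#' overlapping-symptom list (HPO codes plus the diseases each symptom is tied
#' to), the module-to-OMOP routing table, the genotype feature concept map,
#' and the per-domain cohort inclusion criteria. Every row is validated
#' against the code-syntax and uniqueness invariants; a violation aborts with
#' a message naming the file, row, and field.
#'
#' Concept identifiers that are not part of a released OMOP vocabulary are
#' local placeholders in the reserved >= 2,000,000,000 range and carry
#' `placeholder = TRUE`.
#'
#' @param resource_dir directory holding the catalog CSV files; defaults to
#'   the copies shipped with the package.
#' @return an object of class `catalog_bundle`: a list of data frames
#'   `diseases`, `symptoms`, `routes`, `genotype_map`, `criteria`,
#'   `concept_minimap`, `domain_codes`, `narrative_overlaps`.
#' @examples
#' cat <- load_catalogs()
#' subset(cat$diseases, disease_name == "Graves' disease")
#' @export
load_catalogs <- function(resource_dir = catalog_dir()) {
  if (!dir.exists(resource_dir))
    config_error(sprintf("catalog directory does not exist: %s", resource_dir))
  paths <- file.path(resource_dir, CATALOG_FILES)
  names(paths) <- names(CATALOG_FILES)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    config_error(sprintf("missing catalog file(s): %s",
                         paste(basename(missing), collapse = ", ")))

  diseases <- read_csv_strict(paths[["diseases"]],
    c("domain", "disease_group", "disease_name", "icd10gm_code", "orpha_code"))
  validate_diseases(diseases)
  diseases$orpha_norm <- orpha_normalize(diseases$orpha_code)

  symptoms <- read_csv_strict(paths[["symptoms"]],
    c("group", "symptom_name", "hpo_code", "diseases_verbatim", "disease_keys"))
  validate_symptoms(symptoms, diseases)

  routes <- read_csv_strict(paths[["routes"]],
    c("rdcdm_module", "omop_tables", "vocabularies", "default_table"))
  validate_routes(routes)

  gmap <- read_csv_strict(paths[["genotype_map"]],
    c("source_feature", "target_concept_id", "target_concept_name",
      "target_table", "vocabulary", "value_kind", "placeholder",
      "value_low", "value_high"))
  gmap$target_concept_id <- as.integer(gmap$target_concept_id)
  gmap$placeholder <- gmap$placeholder == "true"
  gmap$value_low <- suppressWarnings(as.numeric(gmap$value_low))
  gmap$value_high <- suppressWarnings(as.numeric(gmap$value_high))
  validate_genotype_map(gmap)

  criteria <- read_csv_strict(paths[["criteria"]],
    c("domain", "min_age_years", "window_start", "window_end", "icd10_patterns"))
  criteria$min_age_years <- as.integer(criteria$min_age_years)
  validate_criteria_table(criteria)

  minimap_path <- file.path(resource_dir, "concept_minimap.csv")
  minimap <- if (file.exists(minimap_path)) {
    mm <- read_csv_strict(minimap_path,
      c("source_code", "source_vocabulary_id", "target_concept_id",
        "target_concept_name", "placeholder"))
    mm$target_concept_id <- as.integer(mm$target_concept_id)
    mm$placeholder <- mm$placeholder == "true"
    mm
  } else {
    data.frame(source_code = character(0), source_vocabulary_id = character(0),
               target_concept_id = integer(0), target_concept_name = character(0),
               placeholder = logical(0), stringsAsFactors = FALSE)
  }

  dc_path <- file.path(resource_dir, "domain_codes.csv")
  domain_codes <- if (file.exists(dc_path)) {
    dc <- read_csv_strict(dc_path,
      c("domain", "kind", "code", "system", "description", "unit", "low", "high"))
    dc$low <- suppressWarnings(as.numeric(dc$low))
    dc$high <- suppressWarnings(as.numeric(dc$high))
    dc
  } else NULL

  no_path <- file.path(resource_dir, "narrative_overlaps.csv")
  narrative <- if (file.exists(no_path)) {
    read_csv_strict(no_path, c("group_set", "symptom_name", "hpo_code"))
  } else NULL

  structure(list(diseases = diseases, symptoms = symptoms, routes = routes,
                 genotype_map = gmap, criteria = criteria,
                 concept_minimap = minimap, domain_codes = domain_codes,
                 narrative_overlaps = narrative),
            class = "catalog_bundle")
}

orpha_normalize <- function(x) {
  out <- rep(NA_integer_, length(x))
  has <- !is.na(x) & nzchar(x)
  digits <- gsub("[^0-9]", "", x[has])
  out[has] <- suppressWarnings(as.integer(digits))
  out
}

validate_diseases <- function(d) {
  bad <- which(!is_icd10gm(d$icd10gm_code))
  if (length(bad))
    validation_error(sprintf(
      "diseases.csv row %d: field icd10gm_code has malformed code '%s'",
      bad[1], d$icd10gm_code[bad[1]]))
  has_orpha <- !is.na(d$orpha_code) & nzchar(d$orpha_code)
  bad <- which(has_orpha & !grepl("^ORPHA:[0-9][0-9,]*$", d$orpha_code))
  if (length(bad))
    validation_error(sprintf(
      "diseases.csv row %d: field orpha_code has malformed code '%s'",
      bad[1], d$orpha_code[bad[1]]))
  key <- paste(d$domain, d$disease_name, d$icd10gm_code, sep = "\x1f")
  if (anyDuplicated(key))
    validation_error(sprintf(
      "diseases.csv row %d: duplicate (domain, disease_name, icd10gm_code)",
      which(duplicated(key))[1]))
  if (!all(d$domain %in% RDCDM_DOMAINS))
    validation_error("diseases.csv: field domain has value outside the four domains")
  invisible(d)
}

validate_symptoms <- function(s, diseases) {
  bad <- which(!is_hpo(s$hpo_code))
  if (length(bad))
    validation_error(sprintf(
      "symptoms.csv row %d: field hpo_code has malformed code '%s'",
      bad[1], s$hpo_code[bad[1]]))
  keys <- split_list_col(s$disease_keys)
  empty <- which(!lengths(keys))
  if (length(empty))
    validation_error(sprintf(
      "symptoms.csv row %d: field disease_keys is empty", empty[1]))
  unknown <- setdiff(unique(unlist(keys)), diseases$disease_name)
  if (length(unknown))
    validation_error(sprintf(
      "symptoms.csv: field disease_keys references unknown disease(s): %s",
      paste(unknown, collapse = "; ")))
  invisible(s)
}

validate_routes <- function(r) {
  if (!setequal(r$rdcdm_module, RDCDM_MODULES) || anyDuplicated(r$rdcdm_module))
    validation_error("routes.csv: each of the seven modules must appear exactly once")
  tabs <- unique(unlist(split_list_col(r$omop_tables)))
  bad <- setdiff(tabs, OMOP_EVENT_TABLES)
  if (length(bad))
    validation_error(sprintf("routes.csv: field omop_tables has unknown table(s): %s",
                             paste(bad, collapse = ", ")))
  if (!all(mapply(function(d, t) d %in% t, r$default_table, split_list_col(r$omop_tables))))
    validation_error("routes.csv: default_table must be one of the module's omop_tables")
  invisible(r)
}

validate_genotype_map <- function(g) {
  if (anyDuplicated(g$source_feature))
    validation_error(sprintf("genotype_concept_map.csv row %d: duplicate source_feature",
                             which(duplicated(g$source_feature))[1]))
  bad <- which(is.na(g$target_concept_id) | g$target_concept_id <= 0L)
  if (length(bad))
    validation_error(sprintf(
      "genotype_concept_map.csv row %d: field target_concept_id must be > 0", bad[1]))
  bad <- which(!g$target_table %in% c("measurement", "observation"))
  if (length(bad))
    validation_error(sprintf(
      "genotype_concept_map.csv row %d: field target_table invalid", bad[1]))
  bad <- which(!g$value_kind %in% c("binary", "numeric"))
  if (length(bad))
    validation_error(sprintf(
      "genotype_concept_map.csv row %d: field value_kind invalid", bad[1]))
  invisible(g)
}

validate_criteria_table <- function(cr) {
  ws <- as.Date(cr$window_start); we <- as.Date(cr$window_end)
  if (anyNA(ws) || anyNA(we))
    validation_error("criteria.csv: window dates must be ISO-8601")
  if (any(ws > we)) validation_error("criteria.csv: window_start after window_end")
  if (any(is.na(cr$min_age_years) | cr$min_age_years < 0L))
    validation_error("criteria.csv: field min_age_years must be >= 0")
  pats <- unlist(split_list_col(cr$icd10_patterns))
  bad <- pats[!is_icd10gm(pats)]
  if (length(bad))
    validation_error(sprintf("criteria.csv: malformed ICD-10-GM pattern '%s'", bad[1]))
  invisible(cr)
}

#' @export
print.catalog_bundle <- function(x, ...) {
  cat("<catalog_bundle>\n")
  cat(sprintf("  diseases:     %d entries across %d domains\n",
              nrow(x$diseases), length(unique(x$diseases$domain))))
  cat(sprintf("  symptoms:     %d entries across %d groups\n",
              nrow(x$symptoms), length(unique(x$symptoms$group))))
  cat(sprintf("  routes:       %d module routes\n", nrow(x$routes)))
  cat(sprintf("  genotype map: %d features (%d placeholder ids)\n",
              nrow(x$genotype_map), sum(x$genotype_map$placeholder)))
  cat(sprintf("  criteria:     %d domain rule sets\n", nrow(x$criteria)))
  invisible(x)
}

#' Match an ICD-10-GM code against a code or chapter wildcard
#'
#' A pattern ending in `".-"` stands for the whole three-character category:
#' it matches any code sharing that stem, including the bare stem itself.
#' Any other pattern matches only by exact equality.
#'
#' @param pattern ICD-10-GM code or `".-"` wildcard (recycled).
#' @param code ICD-10-GM code(s) to test.
#' @return logical vector.
#' @examples
#' match_icd10("E05.-", "E05.8")  # TRUE
#' match_icd10("C34.-", "C92.0")  # FALSE
#' @export
match_icd10 <- function(pattern, code) {
  n <- max(length(pattern), length(code))
  pattern <- rep_len(as.character(pattern), n)
  code <- rep_len(as.character(code), n)
  if (any(!is_icd10gm(pattern)))
    value_error(sprintf("match_icd10(): syntactically invalid pattern '%s'",
                        pattern[!is_icd10gm(pattern)][1]))
  if (any(!is_icd10gm(code)))
    value_error(sprintf("match_icd10(): syntactically invalid code '%s'",
                        code[!is_icd10gm(code)][1]))
  wildcard <- endsWith(pattern, ".-")
  out <- pattern == code
  stem_p <- substr(pattern, 1, 3)
  stem_c <- substr(code, 1, 3)
  out[wildcard] <- stem_p[wildcard] == stem_c[wildcard]
  out
}

resolve_groups <- function(catalog, groups) {
  if (is.character(groups)) groups <- as.list(groups)
  if (!is.list(groups) || !length(groups))
    value_error("groups must be a non-empty character vector or list of character vectors")
  known <- unique(catalog$symptoms$group)
  flat <- unlist(groups)
  unknown <- setdiff(flat, known)
  if (length(unknown))
    value_error(sprintf("unknown symptom group(s): %s", paste(unknown, collapse = ", ")))
  groups
}

group_hpo_set <- function(catalog, group_names) {
  sort(unique(catalog$symptoms$hpo_code[catalog$symptoms$group %in% group_names]))
}

#' HPO codes shared by a set of symptom groups
#'
#' Each element of `groups` names one group, or (as a character vector inside
#' a list) a union of groups to be merged before intersecting -- the usual way
#' to treat the two endocrine groups (hyper-/hypothyroidism) as one domain.
#'
#' @param catalog a `catalog_bundle`.
#' @param groups character vector of group names, or list whose elements are
#'   character vectors of group names (each element is unioned, then all
#'   elements are intersected).
#' @return sorted character vector of shared HPO codes.
#' @examples
#' cat <- load_catalogs()
#' shared_symptoms(cat, c("Gastroenterology", "Pneumonology"))
#' @export
shared_symptoms <- function(catalog, groups) {
  groups <- resolve_groups(catalog, groups)
  sets <- lapply(groups, function(g) group_hpo_set(catalog, g))
  Reduce(intersect, sets)
}

#' Routing of one model module into OMOP tables and vocabularies
#'
#' @param catalog a `catalog_bundle`.
#' @param module one of `"Person"`, `"Diagnosis"`, `"Procedure"`,
#'   `"LaboratoryFindings"`, `"Medication"`, `"Genotype"`, `"Phenotype"`.
#' @return list with `rdcdm_module`, `omop_tables` (ordered as bundled),
#'   `vocabularies`, and `default_table` (the table this package writes to).
#' @export
route_for_module <- function(catalog, module) {
  module <- match.arg(module, RDCDM_MODULES)
  row <- catalog$routes[catalog$routes$rdcdm_module == module, , drop = FALSE]
  list(rdcdm_module = module,
       omop_tables = split_list_col(row$omop_tables)[[1]],
       vocabularies = split_list_col(row$vocabularies)[[1]],
       default_table = row$default_table)
}

#' Construct cohort inclusion criteria
#'
#' @param min_age_years minimum age in completed years at visit admission.
#' @param window_start,window_end inclusive admission/discharge date window.
#' @param icd10_patterns character vector of ICD-10-GM codes or `".-"`
#'   chapter wildcards; a patient qualifies with at least one matching
#'   diagnosis.
#' @return object of class `cohort_criteria`.
#' @export
cohort_criteria <- function(min_age_years, window_start, window_end, icd10_patterns) {
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (is.na(window_start) || is.na(window_end))
    value_error("cohort_criteria(): window dates must parse as dates")
  if (window_start > window_end)
    value_error("cohort_criteria(): window_start must be <= window_end")
  min_age_years <- as.integer(min_age_years)
  if (is.na(min_age_years) || min_age_years < 0L)
    value_error("cohort_criteria(): min_age_years must be >= 0")
  icd10_patterns <- as.character(icd10_patterns)
  bad <- icd10_patterns[!is_icd10gm(icd10_patterns)]
  if (length(bad))
    value_error(sprintf("cohort_criteria(): malformed ICD-10-GM pattern '%s'", bad[1]))
  structure(list(min_age_years = min_age_years, window_start = window_start,
                 window_end = window_end, icd10_patterns = icd10_patterns),
            class = "cohort_criteria")
}

#' Bundled inclusion criteria for one domain
#'
#' @param catalog a `catalog_bundle`.
#' @param domain one of the four domains.
#' @return a `cohort_criteria` object.
#' @export
default_criteria <- function(catalog, domain) {
  domain <- match.arg(domain, RDCDM_DOMAINS)
  row <- catalog$criteria[catalog$criteria$domain == domain, , drop = FALSE]
  if (!nrow(row)) config_error(sprintf("no bundled criteria for domain '%s'", domain))
  cohort_criteria(row$min_age_years, row$window_start, row$window_end,
                  split_list_col(row$icd10_patterns)[[1]])
}

#' @export
print.cohort_criteria <- function(x, ...) {
  cat(sprintf("<cohort_criteria> age >= %d at admission; stay within [%s, %s]; %d diagnosis pattern(s)\n",
              x$min_age_years, format(x$window_start), format(x$window_end),
              length(x$icd10_patterns)))
  invisible(x)
}

## Exact-match lookup into the bundled mini concept map; unmapped -> 0.
minimap_lookup <- function(catalog, codes, vocabulary) {
  mm <- catalog$concept_minimap
  mm <- mm[mm$source_vocabulary_id == vocabulary, , drop = FALSE]
  idx <- match(codes, mm$source_code)
  out <- mm$target_concept_id[idx]
  out[is.na(out)] <- 0L
  out
}
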
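## Seeded synthetic cohorts standing in for the two hospitals' source data.
## The generator reproduces structure, not epidemiology: diagnoses are drawn
## from the bundled per-domain disease list (codes exactly as catalogued),
## symptoms only from the catalogued symptom-disease links, laboratory /
## medication / procedure codes from the small bundled per-domain lists, and
## every emitted code or feature is resolvable in the catalogs -- which is
## what makes a 100% mapping rate a reproducible property of the clean
## generator rather than an empirical claim.

random_dates <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  as.Date(sample(0:(as.integer(to - from)), n, replace = TRUE), origin = from)
}

## Birth date at least `age` completed years before `on` (age * 366 days is
## a safe lower bound whatever the leap-year layout), jittered within a year
## so birthdays spread over the calendar.
birth_for_age <- function(on, age) {
  offset <- sample(0:364, length(on), replace = TRUE)
  on - age * 366L - offset
}

#' Generate a seeded synthetic cohort for one domain
#'
#' Every patient receives at least one inpatient visit inside the criteria
#' window at an age of at least the criteria threshold, a diagnosis drawn
#' from the domain's bundled disease list (ICD-10-GM code exactly as
#' catalogued, Orpha code carried along), symptoms sampled only from the
#' bundled entries linked to the assigned disease, and a few laboratory /
#' medication / procedure records from the bundled per-domain code lists.
#' Race and ethnicity are populated for hematology-style cohorts only.
#' Output is deterministic given `seed`.
#'
#' @param domain one of `"endocrinology"`, `"gastroenterology"`,
#'   `"pneumonology"`, `"hematology"`.
#' @param n_patients number of patients (>= 0).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param catalog a `catalog_bundle` (defaults to the bundled catalogs).
#' @param criteria a `cohort_criteria`; defaults to the bundled per-domain
#'   criteria.
#' @param symptom_prob inclusion probability per linked symptom (default
#'   0.5; structural, no epidemiological claim).
#' @param dirty_fraction fraction (0..1) of phenotype records given
#'   malformed HPO codes and genotype records given unmapped feature names,
#'   for negative-path testing; 0 recovers the clean generator.
#' @param site provenance label for the emitting site.
#' @return a validated `rdcdm_bundle`.
#' @export
generate_domain_cohort <- function(domain, n_patients, seed = 1L,
                                   catalog = load_catalogs(), criteria = NULL,
                                   symptom_prob = 0.5, dirty_fraction = 0,
                                   site = "SITE-A") {
  domain <- match.arg(domain, RDCDM_DOMAINS)
  if (!is.numeric(n_patients) || n_patients < 0)
    value_error("n_patients must be >= 0")
  n <- as.integer(n_patients)
  if (is.null(criteria)) criteria <- default_criteria(catalog, domain)
  prov <- list(domain = domain, site = site, seed = seed)
  if (n == 0L) return(rdcdm_bundle(provenance = prov))

  with_seed(seed, {
    diseases <- catalog$diseases[catalog$diseases$domain == domain, , drop = FALSE]
    person_id <- sprintf("%s-%s-%05d", site, toupper(substr(domain, 1, 3)), seq_len(n))

    ## visits: one guaranteed in-window qualifying visit per patient
    admission <- random_dates(n, criteria$window_start, criteria$window_end - 30L)
    stay <- sample(0:21, n, replace = TRUE)
    discharge <- pmin(admission + stay, criteria$window_end)
    age_adm <- sample(criteria$min_age_years:90, n, replace = TRUE)
    birth <- birth_for_age(admission, age_adm)
    gender <- sample(c("female", "male"), n, replace = TRUE)

    dz <- diseases[sample.int(nrow(diseases), n, replace = TRUE), , drop = FALSE]

    race <- ethnicity <- rep(NA_character_, n)
    if (domain == "hematology") {
      race <- sample(c("White", "Black or African American", "Asian", "Other"),
                     n, replace = TRUE, prob = c(0.8, 0.08, 0.07, 0.05))
      ethnicity <- sample(c("Not Hispanic or Latino", "Hispanic or Latino"),
                          n, replace = TRUE, prob = c(0.95, 0.05))
    }

    person <- data.frame(
      person_id = person_id, gender = gender, birth_date = birth,
      age_at_diagnosis = age_in_years(birth, admission),
      postal_code = sprintf("%05d", sample.int(99998, n, replace = TRUE)),
      race = race, ethnicity = ethnicity, stringsAsFactors = FALSE)

    visit <- data.frame(
      visit_id = paste0(person_id, "-V01"), person_id = person_id,
      admission_date = admission, discharge_date = discharge,
      visit_kind = sample(VISIT_KINDS, n, replace = TRUE, prob = c(0.85, 0.15)),
      stringsAsFactors = FALSE)

    diagnosis <- data.frame(
      person_id = person_id, visit_id = visit$visit_id,
      icd10gm_code = dz$icd10gm_code,
      orpha_code = ifelse(is.na(dz$orpha_code) | !nzchar(dz$orpha_code),
                          NA_character_, dz$orpha_code),
      diagnosis_date = admission, stringsAsFactors = FALSE)

    ## symptoms only where the catalog ties them to the assigned disease
    sym <- catalog$symptoms
    sym_keys <- split_list_col(sym$disease_keys)
    phenotype <- do.call(rbind, lapply(seq_len(n), function(i) {
      linked <- which(vapply(sym_keys, function(k) dz$disease_name[i] %in% k, logical(1)))
      if (!length(linked)) return(NULL)
      take <- linked[stats::runif(length(linked)) < symptom_prob]
      if (!length(take)) return(NULL)
      data.frame(person_id = person_id[i], visit_id = visit$visit_id[i],
                 hpo_code = sym$hpo_code[take], observed = TRUE,
                 noted_at = admission[i], stringsAsFactors = FALSE)
    }))

    dc <- catalog$domain_codes
    if (is.null(dc)) config_error("bundled domain_codes.csv missing; cannot synthesize labs/medications")
    dc <- dc[dc$domain == domain, , drop = FALSE]
    labs_codes <- dc[dc$kind == "lab", , drop = FALSE]
    n_lab <- sample(0:3, n, replace = TRUE)
    li <- rep(seq_len(n), n_lab)
    lab_row <- sample.int(nrow(labs_codes), length(li), replace = TRUE)
    laboratory <- data.frame(
      person_id = person_id[li], visit_id = visit$visit_id[li],
      loinc_code = labs_codes$code[lab_row],
      value = round(stats::runif(length(li), labs_codes$low[lab_row],
                                 labs_codes$high[lab_row]), 2),
      ucum_unit = labs_codes$unit[lab_row], measured_at = admission[li],
      stringsAsFactors = FALSE)

    med_codes <- dc$code[dc$kind == "medication"]
    mi <- which(stats::runif(n) < 0.6)
    medication <- data.frame(
      person_id = person_id[mi], visit_id = visit$visit_id[mi],
      atc_code = sample(med_codes, length(mi), replace = TRUE),
      rxnorm_code = rep(NA_character_, length(mi)), start_date = admission[mi],
      stringsAsFactors = FALSE)

    proc_codes <- dc$code[dc$kind == "procedure"]
    pi_ <- which(stats::runif(n) < 0.4)
    procedure <- data.frame(
      person_id = person_id[pi_], visit_id = visit$visit_id[pi_],
      ops_code = sample(proc_codes, length(pi_), replace = TRUE),
      procedure_date = admission[pi_], stringsAsFactors = FALSE)

    if (dirty_fraction > 0 && !is.null(phenotype) && nrow(phenotype)) {
      k <- which(stats::runif(nrow(phenotype)) < dirty_fraction)
      phenotype$hpo_code[k] <- sprintf("HP:%d", seq_along(k))  # malformed on purpose
    }

    bundle <- rdcdm_bundle(person = person, visit = visit, diagnosis = diagnosis,
                           procedure = procedure, laboratory = laboratory,
                           medication = medication, phenotype = phenotype,
                           provenance = prov)
    canonicalize_bundle(bundle)
  })
}

#' Generate the synthetic hematology validation dataset
#'
#' Emulates an AML cohort shaped like the validation use case: by default
#' 1,674 patients and a wide file of 124 clinical and gene-mutation feature
#' columns (one row per patient), every column pre-registered in the bundled
#' genotype concept map and always including the four CEBPA-derived features
#' (`CEBPA.bZIP`, `CEBPA.bZIP.inframe`, `CEBPA.TAD`, `CEBPASTAT`). Each
#' patient carries the AML diagnosis C92.0 and populated race/ethnicity.
#' The wide file is also melted into the bundle's genotype module so both
#' ETL entry points see the same records.
#'
#' @param n_patients number of patients (default 1674).
#' @param n_features number of feature columns (default 124; must be >= 5
#'   and at most the bundled concept-map size).
#' @param seed integer seed.
#' @param catalog a `catalog_bundle`.
#' @param mutation_prob probability that a binary mutation feature is
#'   positive (default 0.2; structural choice).
#' @param dirty_fraction fraction of feature columns renamed to names absent
#'   from the concept map (negative-path testing); 0 keeps every column
#'   mappable.
#' @param out_dir optional directory; when given, the bundle and the wide
#'   file (`genotype_wide.csv`) are written there.
#' @return list with `bundle` (an `rdcdm_bundle`), `wide` (the wide data
#'   frame), and `features` (the feature column names).
#' @export
generate_hematology <- function(n_patients = 1674L, n_features = 124L, seed = 1L,
                                catalog = load_catalogs(), mutation_prob = 0.2,
                                dirty_fraction = 0, out_dir = NULL) {
  map <- catalog$genotype_map
  cebpa <- c("CEBPA.bZIP", "CEBPA.bZIP.inframe", "CEBPA.TAD", "CEBPASTAT")
  if (!is.numeric(n_features) || n_features < 5)
    value_error("n_features must be >= 5 (the four CEBPA features plus at least one more)")
  if (n_features > nrow(map))
    value_error(sprintf(
      "n_features (%d) exceeds the bundled genotype concept map (%d features): %s",
      as.integer(n_features), nrow(map),
      paste(utils::head(map$source_feature, 10), collapse = ", ")))
  n_features <- as.integer(n_features)
  n <- as.integer(n_patients)

  bundle <- generate_domain_cohort("hematology", n, seed = seed, catalog = catalog)
  features <- c(cebpa, setdiff(map$source_feature, cebpa)[seq_len(n_features - 4L)])

  wide <- with_seed(seed + 1L, {
    w <- data.frame(person_id = bundle$person$person_id, stringsAsFactors = FALSE)
    for (f in features) {
      row <- map[map$source_feature == f, , drop = FALSE]
      w[[f]] <- if (row$value_kind == "binary") {
        sample(c("positive", "negative"), n, replace = TRUE,
               prob = c(mutation_prob, 1 - mutation_prob))
      } else {
        as.character(round(stats::runif(n, row$value_low, row$value_high), 2))
      }
    }
    if (dirty_fraction > 0) {
      k <- which(stats::runif(length(features)) < dirty_fraction)
      names(w)[1L + k] <- sprintf("UNMAPPED_FEATURE_%d", k)
    }
    w
  })

  if (n > 0L) {
    visit_lookup <- setNames(bundle$visit$visit_id, bundle$visit$person_id)
    date_lookup <- setNames(bundle$visit$admission_date, bundle$visit$person_id)
    geno <- melt_genotype_wide(wide, visit_lookup = visit_lookup)
    geno$assayed_at <- as.Date(unname(date_lookup[geno$person_id]),
                               origin = "1970-01-01")
    bundle$genotype <- coerce_module(geno, "genotype")
    bundle <- canonicalize_bundle(bundle)
  }

  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir)
    write_csv_stable(wide, file.path(out_dir, "genotype_wide.csv"))
  }
  list(bundle = bundle, wide = wide, features = setdiff(names(wide), "person_id"))
}
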
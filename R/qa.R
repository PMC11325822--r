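## QA reporting: per-domain patient counts, symptom-overlap tables with the
## published narrative surfaced against the transcription, and the mapping
## success summary that gates a pipeline run.

#' Per-domain patient counts and their total
#'
#' Accepts either a list of bundles (domain read from each bundle's
#' provenance, or from the list names) or a named numeric vector of already
#' counted cohort sizes -- the latter lets externally reported counts be
#' totalled through the same arithmetic.
#'
#' @param x list of `rdcdm_bundle` objects, or named numeric vector of
#'   per-domain patient counts.
#' @return data frame of class `cohort_summary` with one row per domain and
#'   a `total` attribute equal to the arithmetic sum of the parts.
#' @examples
#' cohort_summary(c(endocrinology = 41559, gastroenterology = 1324,
#'                  pneumonology = 17141, hematology = 1673))
#' @export
cohort_summary <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      value_error("cohort_summary(): numeric input must be a named vector of counts")
    df <- data.frame(domain = names(x), n_patients = as.numeric(unname(x)),
                     stringsAsFactors = FALSE)
  } else {
    if (inherits(x, "rdcdm_bundle")) x <- list(x)
    if (!is.list(x) || !all(vapply(x, inherits, logical(1), "rdcdm_bundle")))
      value_error("cohort_summary(): expected bundles or a named count vector")
    doms <- vapply(seq_along(x), function(i) {
      prov <- attr(x[[i]], "provenance")
      prov$domain %||% names(x)[i] %||% sprintf("bundle_%d", i)
    }, character(1))
    counts <- vapply(x, function(b) length(unique(b$person$person_id)), numeric(1))
    df <- stats::aggregate(list(n_patients = counts), by = list(domain = doms), FUN = sum)
  }
  structure(df, total = sum(df$n_patients), class = c("cohort_summary", "data.frame"))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print.data.frame(as.data.frame(x))
  cat(sprintf("  total: %s\n", format(attr(x, "total"), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

canonical_group_sets <- function(catalog) {
  ## "Endocrinology" at domain level means the union of its two groups.
  list(Gastroenterology = "Gastroenterology",
       Pneumonology = "Pneumonology",
       Endocrinology = c("Endocrinology: Hyperthyroidism", "Endocrinology: Hypothyroidism"),
       Hematology = "Hematology")
}

#' Pairwise and full symptom overlaps between groups
#'
#' Computes, from the bundled symptom transcription, the HPO-code
#' intersection of every pair of the requested groups and of all of them
#' together. Where a bundled narrative claim about an overlap disagrees
#' with the computed set, the disagreement is listed, not silently
#' corrected: the transcription is the ground truth of this package, the
#' narrative is carried for transparency.
#'
#' @param catalog a `catalog_bundle`.
#' @param groups named list of group unions (as for [shared_symptoms()]);
#'   defaults to the four domain-level sets with the two endocrine groups
#'   unioned.
#' @return list of class `symptom_overlap_report` with elements `pairs`
#'   (data frame: group_a, group_b, hpo_codes, symptom names), `full`
#'   (character vector), and `narrative_discrepancies` (data frame or NULL).
#' @export
symptom_overlap_report <- function(catalog, groups = canonical_group_sets(catalog)) {
  if (!length(groups)) value_error("symptom_overlap_report(): empty group set")
  if (is.character(groups)) groups <- setNames(as.list(groups), groups)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    value_error("symptom_overlap_report(): groups must be named")
  lapply(groups, function(g) resolve_groups(catalog, g))

  hpo_names <- function(codes) {
    nm <- catalog$symptoms$symptom_name[match(codes, catalog$symptoms$hpo_code)]
    paste(sprintf("%s (%s)", nm, codes), collapse = "; ")
  }
  nms <- names(groups)
  pairs <- if (length(groups) >= 2L) {
    cmb <- utils::combn(seq_along(groups), 2L)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      i1 <- cmb[1, j]; i2 <- cmb[2, j]
      codes <- shared_symptoms(catalog, list(groups[[i1]], groups[[i2]]))
      data.frame(group_a = nms[i1], group_b = nms[i2],
                 n_shared = length(codes),
                 hpo_codes = paste(codes, collapse = ";"),
                 symptoms = hpo_names(codes), stringsAsFactors = FALSE)
    }))
  } else NULL
  full <- shared_symptoms(catalog, unname(groups))

  discrepancies <- NULL
  narr <- catalog$narrative_overlaps
  if (!is.null(narr)) {
    sets <- strsplit(narr$group_set, "|", fixed = TRUE)
    rows <- lapply(unique(narr$group_set), function(gs) {
      members <- strsplit(gs, "|", fixed = TRUE)[[1]]
      if (!all(members %in% nms)) return(NULL)
      claimed <- narr[narr$group_set == gs, , drop = FALSE]
      computed <- shared_symptoms(catalog, groups[members])
      claimed_codes <- claimed$hpo_code[nzchar(claimed$hpo_code)]
      miss <- setdiff(claimed_codes, computed)
      uncoded <- claimed$symptom_name[!nzchar(claimed$hpo_code)]
      if (!length(miss) && !length(uncoded)) return(NULL)
      data.frame(group_set = gs,
                 claimed_not_computed = paste(c(miss, uncoded), collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) discrepancies <- do.call(rbind, rows)
  }
  structure(list(pairs = pairs, full = full,
                 narrative_discrepancies = discrepancies),
            class = "symptom_overlap_report")
}

#' @export
print.symptom_overlap_report <- function(x, ...) {
  cat("<symptom_overlap_report>\n")
  if (!is.null(x$pairs)) {
    cat("pairwise overlaps:\n")
    print.data.frame(x$pairs[, c("group_a", "group_b", "n_shared", "hpo_codes")])
  }
  cat(sprintf("full intersection: %s\n",
              if (length(x$full)) paste(x$full, collapse = ", ") else "(empty)"))
  if (!is.null(x$narrative_discrepancies)) {
    cat("narrative claims not supported by the transcription:\n")
    print.data.frame(x$narrative_discrepancies)
  }
  invisible(x)
}

#' Summarize a mapping report
#'
#' @param report a `mapping_report`.
#' @param threshold optional minimum success rate in percent; when given,
#'   `pass` is FALSE below it (CLI exit gate).
#' @param format `"text"` or `"json"` for the `rendered` element.
#' @return list with `counts`, `success_rate` (percent), `pass`, `rendered`.
#' @export
mapping_success_summary <- function(report, threshold = NULL, format = c("text", "json")) {
  stopifnot(inherits(report, "mapping_report"))
  format <- match.arg(format)
  pass <- if (is.null(threshold)) TRUE else report$success_rate >= threshold
  payload <- list(mapped = unname(report$counts[["mapped"]]),
                  unmapped = unname(report$counts[["unmapped"]]),
                  rejected = unname(report$counts[["rejected"]]),
                  success_rate = round(report$success_rate, 1),
                  pass = pass)
  rendered <- if (format == "json") {
    jsonlite::toJSON(payload, auto_unbox = TRUE)
  } else {
    paste0(sprintf("mapped: %d\nunmapped: %d\nrejected: %d\nsuccess_rate: %.1f%%",
                   payload$mapped, payload$unmapped, payload$rejected,
                   payload$success_rate),
           if (!is.null(threshold))
             sprintf("\nthreshold: %.1f%% -> %s", threshold,
                     if (pass) "PASS" else "FAIL") else "")
  }
  c(payload, list(rendered = rendered))
}
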
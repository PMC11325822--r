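#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can distinguish bad data from bad usage.
rarecdm_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "rarecdm_error"), call = call))
}

validation_error <- function(message) rarecdm_error(message, "rarecdm_validation_error")
config_error    <- function(message) rarecdm_error(message, "rarecdm_config_error")
value_error     <- function(message) rarecdm_error(message, "rarecdm_value_error")
integrity_error <- function(message) rarecdm_error(message, "rarecdm_integrity_error")
parse_error     <- function(message) rarecdm_error(message, "rarecdm_parse_error")

ICD10GM_REGEX <- "^[A-Z][0-9]{2}(\\.([0-9A-Za-z]{1,2}|-))?$"
HPO_REGEX     <- "^HP:[0-9]{7}$"

is_icd10gm <- function(x) !is.na(x) & grepl(ICD10GM_REGEX, x)
is_hpo     <- function(x) !is.na(x) & grepl(HPO_REGEX, x)

## Split a semicolon-delimited list cell into a character vector.
split_list_col <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

## Age in completed calendar years at `on` for someone born on `birth`.
age_in_years <- function(birth, on) {
  birth <- as.Date(birth); on <- as.Date(on)
  by <- as.integer(format(birth, "%Y")); oy <- as.integer(format(on, "%Y"))
  bm <- as.integer(format(birth, "%m")); om <- as.integer(format(on, "%m"))
  bd <- as.integer(format(birth, "%d")); od <- as.integer(format(on, "%d"))
  oy - by - as.integer(om < bm | (om == bm & od < bd))
}

## 32-bit FNV-1a over UTF-8 bytes; used for salted, stable pseudonyms
## (no cryptographic claim -- linkage keys, not secrets).
fnv1a32 <- function(x) {
  ## 32-bit arithmetic carried in doubles; the multiply is split into
  ## 16-bit halves so intermediates stay below 2^53 (no precision loss).
  prime <- 16777619
  vapply(x, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(paste0(s))))
    h <- 2166136261
    for (b in bytes) {
      lo <- h %% 256
      h <- h - lo + bitwXor(lo, b)
      h_hi <- floor(h / 65536)
      h <- (((h_hi * prime) %% 65536) * 65536 + (h %% 65536) * prime) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Pseudonymize identifiers with a salted stable hash
#'
#' External person/visit identifiers must never enter a bundle verbatim.
#' The same (id, salt) pair always yields the same pseudonym, so records
#' belonging to one patient stay linkable after pseudonymization.
#'
#' @param ids character vector of source identifiers.
#' @param salt single string mixed into the hash; keep it outside the data.
#' @param prefix prefix for the generated pseudonyms.
#' @return character vector of pseudonyms, same length as `ids`.
#' @export
pseudonymize_id <- function(ids, salt, prefix = "PSN") {
  if (!is.character(salt) || length(salt) != 1L || !nzchar(salt))
    value_error("pseudonymize_id(): 'salt' must be a non-empty string")
  sprintf("%s-%08X", prefix, fnv1a32(paste0(salt, "\x1f", ids)))
}

## Deterministic CSV writer: fixed column order, "." decimal separator,
## no scientific notation, LF line endings, UTF-8. Identical data frames
## serialize to identical bytes.
write_csv_stable <- function(df, path) {
  df2 <- df
  for (nm in names(df2)) {
    col <- df2[[nm]]
    if (inherits(col, "Date")) {
      df2[[nm]] <- ifelse(is.na(col), NA_character_, format(col, "%Y-%m-%d"))
    } else if (is.numeric(col) && !is.integer(col)) {
      df2[[nm]] <- ifelse(is.na(col), NA_character_,
                          format(col, scientific = FALSE, trim = TRUE, drop0trailing = TRUE))
    } else if (is.logical(col)) {
      df2[[nm]] <- ifelse(is.na(col), NA_character_, ifelse(col, "true", "false"))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df2, con, sep = ",", row.names = FALSE, col.names = TRUE,
                     qmethod = "double", na = "", eol = "\n",
                     fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

read_csv_strict <- function(path, expected_cols = NULL) {
  if (!file.exists(path)) config_error(sprintf("required file missing: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(expected_cols)) {
    extra <- setdiff(names(df), expected_cols)
    missing <- setdiff(expected_cols, names(df))
    if (length(extra))
      parse_error(sprintf("%s: unknown column(s): %s", basename(path), paste(extra, collapse = ", ")))
    if (length(missing))
      parse_error(sprintf("%s: missing column(s): %s", basename(path), paste(missing, collapse = ", ")))
    df <- df[, expected_cols, drop = FALSE]
  }
  df
}

## Run `expr` with a locally seeded RNG and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    value_error("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
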
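#' Read / write a cohort as long-format CSV
#'
#' The on-disk contract is a UTF-8, comma-delimited, header-keyed CSV with
#' exactly the columns `rater_id, lesion_id, session, raw_choice, diagnosis,
#' confidence, perceived_ai_dx, perceived_ai_conf, algorithmic_ai_dx,
#' histology, expertise` (any column order); structurally absent fields are
#' empty strings. Reading validates the records, so `read_cohort_csv()`
#' only returns a valid cohort. The round trip
#' `read_cohort_csv(write_cohort_csv(cohort))` is the identity.
#'
#' @param path File path.
#' @return `read_cohort_csv()`: a validated `cohort`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rec <- fread(path, colClasses = "character", encoding = "UTF-8",
               na.strings = NULL)
  missing_cols <- setdiff(COHORT_COLUMNS, names(rec))
  if (length(missing_cols) > 0L) {
    stop("cohort CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  validate_cohort(rec)
}

#' @param cohort A validated `cohort`.
#' @rdname read_cohort_csv
#' @return `write_cohort_csv()`: `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot_cohort(cohort)
  rec <- copy(cohort$records)
  for (col in names(rec)) data.table::set(rec, j = col, value = {
    x <- rec[[col]]; x[is.na(x)] <- ""; x
  })
  setcolorder(rec, COHORT_COLUMNS)
  setorder(rec, rater_id, lesion_id, session)
  fwrite(rec, path, quote = FALSE)
  invisible(path)
}

#' Read a flat key/value generator config file
#'
#' A minimal YAML-style format: one `key: value` pair per line, `#`
#' comments, blank lines ignored. Vector-valued fields (cutpoint triples,
#' weight quadruples) are comma-separated; weights may be written in level
#' order (VeryLow, Low, High, VeryHigh). Unknown keys are rejected. Any key
#' not present keeps its [generator_config()] default.
#'
#' @param path File path.
#' @return A validated `generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- generator_config()
  args <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", sQuote(ln), call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(defaults)) stop("unknown config key: ", key, call. = FALSE)
    args[[key]] <- parse_config_value(key, val, defaults[[key]])
  }
  do.call(generator_config, args)
}

parse_config_value <- function(key, val, default) {
  if (is.logical(default)) return(toupper(val) %in% c("TRUE", "YES", "1"))
  parts <- trimws(strsplit(val, ",")[[1]])
  num <- suppressWarnings(as.numeric(parts))
  if (any(is.na(num))) stop("non-numeric value for config key ", key, ": ", val,
                            call. = FALSE)
  if (length(default) > 1L && !is.null(names(default))) {
    if (length(num) != length(default)) {
      stop(sprintf("config key %s needs %d values", key, length(default)), call. = FALSE)
    }
    names(num) <- names(default)
  }
  num
}

#' Serialize endpoint estimates to JSON
#'
#' @param estimates An `endpoint_estimates` frame.
#' @param path Output path.
#' @param seed Seed recorded alongside the estimates.
#' @return `path`, invisibly.
#' @export
write_estimates_json <- function(estimates, path, seed = NULL) {
  payload <- list(seed = seed,
                  ai_basis = attr(estimates, "ai_basis"),
                  exclusions = attr(estimates, "exclusions"),
                  estimates = as.data.frame(estimates))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
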
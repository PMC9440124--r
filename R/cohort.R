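#' @importFrom data.table data.table as.data.table setkey := .N .SD setcolorder
#'   fwrite fread copy setorder
NULL

COHORT_COLUMNS <- c("rater_id", "lesion_id", "session", "raw_choice",
                    "diagnosis", "confidence", "perceived_ai_dx",
                    "perceived_ai_conf", "algorithmic_ai_dx", "histology",
                    "expertise")

# normalize "" to NA for the structurally-absent fields
blank_to_na <- function(x) {
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

#' Validate long-format trial records into a cohort
#'
#' Checks one row per rater x lesion x session record against the label
#' vocabularies and structural invariants of the paired-session design:
#'
#' * exactly one record per (rater, lesion, session) cell, both sessions
#'   present for every pair;
#' * confidence is `"Uncertain"` iff the diagnosis is `"Uncertain"`;
#' * session-1 records carry no perceived-AI fields, session-2 records carry
#'   a perceived AI diagnosis;
#' * a perceived AI confidence is present iff the perceived AI diagnosis is
#'   determinate;
#' * every lesion has one determinate binary histology and every rater one
#'   expertise label;
#' * if a raw five-way choice is recorded it must collapse to the stored
#'   diagnosis.
#'
#' @param records A data.frame with the columns `rater_id, lesion_id, session,
#'   raw_choice, diagnosis, confidence, perceived_ai_dx, perceived_ai_conf,
#'   algorithmic_ai_dx, histology, expertise`. Empty strings and `NA` both
#'   denote structurally absent values.
#' @return An object of class `"cohort"`: a list with elements `records`
#'   (a keyed data.table), `raters` (named expertise vector), `lesions`
#'   (named histology vector), `n_raters`, `n_lesions`.
#' @export
validate_cohort <- function(records) {
  rec <- as.data.table(records)
  missing_cols <- setdiff(COHORT_COLUMNS, names(rec))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- rec[, COHORT_COLUMNS, with = FALSE]
  for (col in COHORT_COLUMNS) {
    data.table::set(rec, j = col, value = blank_to_na(as.character(rec[[col]])))
  }
  data.table::set(rec, j = "row", value = seq_len(nrow(rec)))

  problems <- character(0)
  note <- function(fmt, rows, ...) {
    if (length(rows) == 0L) return(invisible())
    shown <- paste(utils::head(rows, 5L), collapse = ", ")
    if (length(rows) > 5L) shown <- paste0(shown, ", ...")
    problems <<- c(problems, sprintf(paste0(fmt, " [row(s) %s]"), ..., shown))
  }

  vocab <- list(session = SESSION_LEVELS, raw_choice = RAW_CHOICE_LEVELS,
                diagnosis = DIAGNOSIS_LEVELS, confidence = CONFIDENCE_LEVELS,
                perceived_ai_dx = PERCEIVED_AI_LEVELS,
                perceived_ai_conf = CONFIDENCE_DET_LEVELS,
                algorithmic_ai_dx = ALGORITHMIC_AI_LEVELS,
                histology = HISTOLOGY_LEVELS, expertise = EXPERTISE_LEVELS)
  for (col in names(vocab)) {
    bad <- !is.na(rec[[col]]) & !(rec[[col]] %in% vocab[[col]])
    note("unknown %s label %s", rec$row[bad], col,
         paste(sQuote(unique(rec[[col]][bad])), collapse = ", "))
  }

  req <- c("rater_id", "lesion_id", "session", "diagnosis", "confidence",
           "histology", "expertise")
  for (col in req) note("missing %s", rec$row[is.na(rec[[col]])], col)
  if (length(problems) > 0L) cohort_error(problems)

  # duplicates / completeness over the (rater, lesion, session) lattice
  dup <- rec[, .(n = .N, rows = list(row)), by = .(rater_id, lesion_id, session)][n > 1L]
  if (nrow(dup) > 0L) {
    problems <- c(problems, sprintf("duplicate record for (%s, %s, %s)",
                                    dup$rater_id, dup$lesion_id, dup$session))
  }
  cells <- rec[, .(sessions = list(sort(unique(session)))), by = .(rater_id, lesion_id)]
  incomplete <- cells[vapply(sessions, function(s) !identical(s, c("S1", "S2")), TRUE)]
  if (nrow(incomplete) > 0L) {
    problems <- c(problems, sprintf("missing session record(s) for (%s, %s)",
                                    incomplete$rater_id, incomplete$lesion_id))
  }

  # confidence/diagnosis coupling
  bad <- (rec$diagnosis == "Uncertain") != (rec$confidence == "Uncertain")
  note("confidence must be 'Uncertain' iff diagnosis is 'Uncertain'", rec$row[bad])

  # session structure of the perceived-AI fields
  s1 <- rec$session == "S1"
  note("S1 record carries perceived_ai_dx", rec$row[s1 & !is.na(rec$perceived_ai_dx)])
  note("S1 record carries perceived_ai_conf", rec$row[s1 & !is.na(rec$perceived_ai_conf)])
  note("S2 record lacks perceived_ai_dx", rec$row[!s1 & is.na(rec$perceived_ai_dx)])
  det_ai <- !is.na(rec$perceived_ai_dx) & is_determinate(rec$perceived_ai_dx)
  note("perceived_ai_conf present without determinate perceived_ai_dx",
       rec$row[!is.na(rec$perceived_ai_conf) & !det_ai])
  note("determinate perceived_ai_dx lacks perceived_ai_conf",
       rec$row[det_ai & is.na(rec$perceived_ai_conf)])

  # raw choice, when recorded, must collapse to the stored diagnosis
  has_raw <- !is.na(rec$raw_choice)
  if (any(has_raw)) {
    bad <- has_raw & map_judgment(ifelse(has_raw, rec$raw_choice, "Uncertain")) != rec$diagnosis
    note("raw_choice does not collapse to diagnosis", rec$row[bad])
  }

  # lesion-level and rater-level consistency
  les <- rec[, .(n_hist = data.table::uniqueN(histology),
                 n_alg = data.table::uniqueN(algorithmic_ai_dx, na.rm = TRUE)),
             by = lesion_id]
  if (any(les$n_hist > 1L)) {
    problems <- c(problems, sprintf("lesion %s has conflicting histology",
                                    les$lesion_id[les$n_hist > 1L]))
  }
  if (any(les$n_alg > 1L)) {
    problems <- c(problems, sprintf("lesion %s has conflicting algorithmic_ai_dx",
                                    les$lesion_id[les$n_alg > 1L]))
  }
  rat <- rec[, .(n_exp = data.table::uniqueN(expertise)), by = rater_id]
  if (any(rat$n_exp > 1L)) {
    problems <- c(problems, sprintf("rater %s has conflicting expertise",
                                    rat$rater_id[rat$n_exp > 1L]))
  }

  if (length(problems) > 0L) cohort_error(problems)

  data.table::set(rec, j = "row", value = NULL)
  setkey(rec, rater_id, lesion_id, session)
  raters <- rec[, .(expertise = expertise[1L]), by = rater_id]
  lesions <- rec[, .(histology = histology[1L]), by = lesion_id]
  structure(list(records = rec,
                 raters = stats::setNames(raters$expertise, raters$rater_id),
                 lesions = stats::setNames(lesions$histology, lesions$lesion_id),
                 n_raters = nrow(raters), n_lesions = nrow(lesions)),
            class = "cohort")
}

cohort_error <- function(problems) {
  stop(structure(class = c("cohort_validation_error", "error", "condition"),
                 list(message = paste0("cohort validation failed:\n",
                                       paste0("  - ", problems, collapse = "\n")),
                      call = NULL, problems = problems)))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d raters (%d expert / %d non-expert) x %d lesions x 2 sessions = %d records\n",
              x$n_raters, sum(x$raters == "Expert"), sum(x$raters == "NonExpert"),
              x$n_lesions, nrow(x$records)))
  cat(sprintf("  adenoma prevalence: %.3f\n", mean(x$lesions == "Adenoma")))
  invisible(x)
}

#' Test whether an object is a validated cohort
#'
#' @param x Any object.
#' @return `TRUE` for objects produced by [validate_cohort()].
#' @export
is_cohort <- function(x) inherits(x, "cohort")

stopifnot_cohort <- function(x) {
  if (!is_cohort(x)) stop("expected a validated cohort; run validate_cohort() first",
                          call. = FALSE)
  invisible(x)
}

# wide (rater, lesion) pair view used by the endpoint and calibration modules:
# one row per pair with S1/S2 diagnosis+confidence and the S2 AI fields
pair_table <- function(cohort) {
  rec <- cohort$records
  s1 <- rec[session == "S1", .(rater_id, lesion_id, dx1 = diagnosis, conf1 = confidence)]
  s2 <- rec[session == "S2", .(rater_id, lesion_id, dx2 = diagnosis, conf2 = confidence,
                               perceived_ai_dx, perceived_ai_conf,
                               algorithmic_ai_dx, histology, expertise)]
  out <- merge(s1, s2, by = c("rater_id", "lesion_id"))
  stopifnot(nrow(out) == nrow(rec) / 2L)
  out
}

ai_label_column <- function(pairs, ai_basis = c("perceived", "algorithmic")) {
  ai_basis <- match.arg(ai_basis)
  lab <- if (ai_basis == "perceived") pairs$perceived_ai_dx else pairs$algorithmic_ai_dx
  if (ai_basis == "perceived" && all(is.na(lab))) {
    stop("ai_basis = 'perceived' but the cohort has no perceived AI fields", call. = FALSE)
  }
  lab
}
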
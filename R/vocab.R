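#' Label vocabularies
#'
#' Canonical label sets used throughout the package. Raters classify each
#' lesion with a five-way forced choice that is collapsed to a three-level
#' optical diagnosis; confidence is reported on four levels, with a fifth
#' "Uncertain" level reserved for uncertain diagnoses; the AI advice comes in
#' an algorithmic (machine-read) and a perceived (rater-read) form.
#'
#' @format Character vectors of allowed labels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
RAW_CHOICE_LEVELS <- c("Adenoma", "Hyperplastic", "SSL", "Carcinoma", "Uncertain")

#' @rdname vocabularies
#' @export
DIAGNOSIS_LEVELS <- c("Adenoma", "NonAdenoma", "Uncertain")

#' @rdname vocabularies
#' @export
CONFIDENCE_LEVELS <- c("VeryLow", "Low", "High", "VeryHigh", "Uncertain")

#' @rdname vocabularies
#' @export
CONFIDENCE_DET_LEVELS <- c("VeryLow", "Low", "High", "VeryHigh")

#' @rdname vocabularies
#' @export
PERCEIVED_AI_LEVELS <- c("Adenoma", "NonAdenoma", "Uncertain", "NotNoticed")

#' @rdname vocabularies
#' @export
ALGORITHMIC_AI_LEVELS <- c("Adenoma", "NonAdenoma", "Undetermined")

#' @rdname vocabularies
#' @export
HISTOLOGY_LEVELS <- c("Adenoma", "NonAdenoma")

#' @rdname vocabularies
#' @export
EXPERTISE_LEVELS <- c("Expert", "NonExpert")

#' @rdname vocabularies
#' @export
SESSION_LEVELS <- c("S1", "S2")

# labels that carry no determinate Adenoma/NonAdenoma call, across vocabularies
INDETERMINATE_LABELS <- c("Uncertain", "NotNoticed", "Undetermined")

is_determinate <- function(x) !is.na(x) & !(x %in% INDETERMINATE_LABELS)

assert_levels <- function(x, levels, what) {
  bad <- setdiff(unique(x[!is.na(x) & x != ""]), levels)
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s label(s): %s (allowed: %s)",
                 what, paste(sQuote(bad), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Collapse the five-way lesion choice to the three-level optical diagnosis
#'
#' Adenoma and Carcinoma collapse to `"Adenoma"`; Hyperplastic and SSL
#' (sessile serrated lesion) collapse to `"NonAdenoma"`; `"Uncertain"` is kept.
#'
#' @param raw_choice Character vector of five-way choices
#'   (Adenoma, Hyperplastic, SSL, Carcinoma, Uncertain).
#' @return Character vector of three-level diagnoses.
#' @export
#' @examples
#' map_judgment(c("Carcinoma", "SSL", "Uncertain"))
map_judgment <- function(raw_choice) {
  assert_levels(raw_choice, RAW_CHOICE_LEVELS, "raw choice")
  map <- c(Adenoma = "Adenoma", Carcinoma = "Adenoma",
           Hyperplastic = "NonAdenoma", SSL = "NonAdenoma",
           Uncertain = "Uncertain")
  unname(map[raw_choice])
}

#' Map a diagnosis/confidence pair to the 1-9 belief score
#'
#' A discrete belief scale: 9 is a strong belief that the lesion is an
#' adenoma, 1 a strong belief that it is not, 5 an uncertain diagnosis.
#' Adenoma diagnoses occupy 6 (VeryLow) to 9 (VeryHigh); non-adenoma
#' diagnoses mirror them on 4 down to 1. The map is invertible except at 5.
#'
#' @param diagnosis Three-level diagnosis vector.
#' @param confidence Five-level confidence vector; must be `"Uncertain"`
#'   exactly when the diagnosis is `"Uncertain"`.
#' @return Integer vector in 1..9.
#' @seealso [score_to_belief()] for the inverse.
#' @export
#' @examples
#' confidence_score(c("Adenoma", "Uncertain", "NonAdenoma"),
#'                  c("VeryHigh", "Uncertain", "VeryHigh"))
confidence_score <- function(diagnosis, confidence) {
  assert_levels(diagnosis, DIAGNOSIS_LEVELS, "diagnosis")
  assert_levels(confidence, CONFIDENCE_LEVELS, "confidence")
  if (length(diagnosis) != length(confidence)) {
    stop("diagnosis and confidence must have the same length", call. = FALSE)
  }
  mismatch <- (diagnosis == "Uncertain") != (confidence == "Uncertain")
  if (any(mismatch)) {
    stop(sprintf(
      "confidence must be 'Uncertain' iff diagnosis is 'Uncertain' (violated at position(s) %s)",
      paste(utils::head(which(mismatch), 5L), collapse = ", ")), call. = FALSE)
  }
  idx <- match(confidence, CONFIDENCE_DET_LEVELS)  # NA for Uncertain
  out <- integer(length(diagnosis))
  out[diagnosis == "Uncertain"] <- 5L
  ade <- diagnosis == "Adenoma"
  out[ade] <- 5L + idx[ade]           # VeryLow..VeryHigh -> 6..9
  non <- diagnosis == "NonAdenoma"
  out[non] <- 5L - idx[non]           # VeryLow..VeryHigh -> 4..1
  out
}

#' Invert the 1-9 belief score
#'
#' @param score Integer vector in 1..9.
#' @return A data.frame with columns `diagnosis` and `confidence`; score 5
#'   maps back to the (Uncertain, Uncertain) pair.
#' @export
score_to_belief <- function(score) {
  if (any(!score %in% 1:9)) stop("score must be in 1..9", call. = FALSE)
  diagnosis <- ifelse(score > 5, "Adenoma", ifelse(score < 5, "NonAdenoma", "Uncertain"))
  conf_idx <- ifelse(score > 5, score - 5L, 5L - score)
  confidence <- ifelse(score == 5, "Uncertain", CONFIDENCE_DET_LEVELS[pmax(conf_idx, 1L)])
  data.frame(diagnosis = diagnosis, confidence = confidence,
             stringsAsFactors = FALSE)
}

#' Correctness of a diagnosis against binary histology
#'
#' Ground truth is binary, so an `"Uncertain"` diagnosis can never be correct.
#'
#' @param diagnosis Three-level diagnosis vector.
#' @param histology Binary histology vector (`"Adenoma"` / `"NonAdenoma"`).
#' @return Logical vector.
#' @export
is_correct <- function(diagnosis, histology) {
  assert_levels(diagnosis, DIAGNOSIS_LEVELS, "diagnosis")
  assert_levels(histology, HISTOLOGY_LEVELS, "histology")
  diagnosis == histology
}

#' Agreement between a rater's diagnosis and an AI label
#'
#' Agreement is only defined when the AI label is determinate; when the AI
#' label is `"Uncertain"`, `"NotNoticed"` or `"Undetermined"` the result is
#' `NA` and callers must state their exclusion policy. A rater's
#' `"Uncertain"` diagnosis compared against a determinate AI label is a
#' disagreement (`FALSE`): no label match occurred.
#'
#' @param md_dx Rater three-level diagnosis vector.
#' @param ai_dx AI label vector (perceived or algorithmic vocabulary).
#' @return Logical vector with `NA` where agreement is undefined.
#' @export
agreement <- function(md_dx, ai_dx) {
  assert_levels(md_dx, DIAGNOSIS_LEVELS, "diagnosis")
  assert_levels(ai_dx, union(PERCEIVED_AI_LEVELS, ALGORITHMIC_AI_LEVELS), "AI")
  out <- md_dx == ai_dx
  out[!is_determinate(ai_dx)] <- NA
  out
}
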
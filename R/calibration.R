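new_calibration_table <- function(stratifier, cells, overall_p, overall_n) {
  structure(list(stratifier = stratifier,
                 cells = cells,
                 overall = c(proportion = overall_p, n = overall_n)),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, digits = 3, ...) {
  cat(sprintf("<calibration_table> stratified by %s\n", x$stratifier))
  cells <- x$cells
  cells$proportion <- round(cells$proportion, digits)
  print(cells, row.names = FALSE)
  cat(sprintf("  overall: %.3f (n = %d)\n", x$overall[["proportion"]],
              as.integer(x$overall[["n"]])))
  invisible(x)
}

#' Reconstruct an overall proportion from per-level cells
#'
#' The weighted-cell identity: `sum(p_k * n_k) / denominator`. With the
#' default denominator (the cells' own total) this inverts per-level
#' reporting; passing a larger denominator treats the extra trials as
#' failures, e.g. uncertain diagnoses counted as wrong.
#'
#' @param proportion,n Per-level proportions and sample sizes.
#' @param denominator Total count; defaults to `sum(n)`.
#' @return The overall proportion.
#' @export
table_overall <- function(proportion, n, denominator = sum(n)) {
  sum(proportion * n) / denominator
}

#' Accuracy stratified by confidence level
#'
#' For the rater sessions, cells cover the four determinate confidence
#' levels and the overall row covers every rater x lesion trial with
#' uncertain diagnoses counted as wrong (ground truth is binary). For the
#' perceived AI, the standard-accuracy convention applies: trials whose
#' perceived AI label is "Uncertain" or "NotNoticed" are excluded from both
#' the cells and the overall row.
#'
#' @param cohort A validated `cohort`.
#' @param target `"S1"`, `"S2"`, or `"ai_perceived"`.
#' @return A `calibration_table`.
#' @export
accuracy_by_confidence <- function(cohort, target = c("S1", "S2", "ai_perceived")) {
  target <- match.arg(target)
  stopifnot_cohort(cohort)
  rec <- cohort$records
  if (target %in% c("S1", "S2")) {
    ses <- rec[session == target]
    correct <- is_correct(ses$diagnosis, ses$histology)
    cells <- cells_by_level(ses$confidence, correct, CONFIDENCE_DET_LEVELS)
    new_calibration_table(paste0("human_conf_", target), cells,
                          mean(correct), nrow(ses))
  } else {
    ses <- rec[session == "S2"]
    det <- is_determinate(ses$perceived_ai_dx)
    ses <- ses[det]
    correct <- ses$perceived_ai_dx == ses$histology
    cells <- cells_by_level(ses$perceived_ai_conf, correct, CONFIDENCE_DET_LEVELS)
    new_calibration_table("ai_conf", cells, mean(correct), nrow(ses))
  }
}

cells_by_level <- function(level, outcome, levels) {
  out <- lapply(levels, function(l) {
    sel <- level == l
    data.frame(level = l, proportion = if (any(sel)) mean(outcome[sel]) else NA_real_,
               n = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Opinion-switch rate stratified by confidence
#'
#' Candidates are (rater, lesion) pairs whose perceived AI label is
#' determinate and whose session-1 diagnosis differs from it (an uncertain
#' session-1 diagnosis is a disagreement). The cell proportion is the
#' fraction of candidates whose session-2 diagnosis equals the AI label,
#' stratified by the rater's session-1 confidence or by the perceived AI
#' confidence. Under the human-confidence stratifier, uncertain session-1
#' trials fall in no cell but stay in the overall row.
#'
#' @param cohort A validated `cohort`.
#' @param stratifier `"human_conf_S1"` or `"ai_conf"`.
#' @return A `calibration_table`.
#' @export
switch_rate_by_confidence <- function(cohort, stratifier = c("human_conf_S1", "ai_conf")) {
  stratifier <- match.arg(stratifier)
  stopifnot_cohort(cohort)
  pairs <- pair_table(cohort)
  det <- is_determinate(pairs$perceived_ai_dx)
  cand <- pairs[det & dx1 != perceived_ai_dx]
  if (nrow(cand) == 0L) {
    stop(sprintf("no switch candidates: %d pairs had an indeterminate perceived AI label, %d agreed in S1",
                 sum(!det), sum(det) - 0L), call. = FALSE)
  }
  switched <- cand$dx2 == cand$perceived_ai_dx
  strat <- if (stratifier == "human_conf_S1") cand$conf1 else cand$perceived_ai_conf
  cells <- cells_by_level(strat, switched, CONFIDENCE_DET_LEVELS)
  new_calibration_table(stratifier, cells, mean(switched), nrow(cand))
}

#' AI accuracy under the standard and conservative conventions
#'
#' Convention `"s"` (standard): correct determinate judgments over
#' determinate judgments. Convention `"u"` (conservative): correct
#' determinate judgments over all rater x lesion trials, so indeterminate
#' outputs ("Uncertain", "NotNoticed", "Undetermined", pooled) count as
#' errors. The algorithmic basis evaluates the lesion-level machine label
#' once per rater x lesion trial, making the two bases comparable.
#'
#' @param cohort A validated `cohort`.
#' @param basis `"perceived"` or `"algorithmic"`.
#' @param convention `"s"` or `"u"`.
#' @return `c(proportion, n)` where `n` is the denominator used.
#' @export
ai_accuracy <- function(cohort, basis = c("perceived", "algorithmic"),
                        convention = c("s", "u")) {
  basis <- match.arg(basis)
  convention <- match.arg(convention)
  stopifnot_cohort(cohort)
  pairs <- pair_table(cohort)
  lab <- ai_label_column(pairs, basis)
  det <- is_determinate(lab)
  n_correct <- sum(det & lab == pairs$histology)
  denom <- if (convention == "s") sum(det) else nrow(pairs)
  c(proportion = n_correct / denom, n = denom)
}

#' Agreement between perceived and algorithmic AI labels
#'
#' The fraction of session-2 trials where the rater's reading of the device
#' output matches the machine reading. Inclusively, matching indeterminate
#' sides ("Uncertain"/"NotNoticed" vs "Undetermined") count as agreement;
#' with `exclude_uncertain` any trial with an indeterminate side on either
#' basis is dropped first.
#'
#' @param cohort A validated `cohort`.
#' @param exclude_uncertain Drop trials with an indeterminate label.
#' @return The agreement proportion.
#' @export
perceived_vs_algorithmic_agreement <- function(cohort, exclude_uncertain = FALSE) {
  stopifnot_cohort(cohort)
  pairs <- pair_table(cohort)
  per_det <- is_determinate(pairs$perceived_ai_dx)
  alg_det <- is_determinate(pairs$algorithmic_ai_dx)
  if (exclude_uncertain) {
    keep <- per_det & alg_det
    mean(pairs$perceived_ai_dx[keep] == pairs$algorithmic_ai_dx[keep])
  } else {
    agree <- (per_det & alg_det & pairs$perceived_ai_dx == pairs$algorithmic_ai_dx) |
      (!per_det & !alg_det)
    mean(agree)
  }
}

#' Average pairwise inter-rater agreement on the perceived AI label
#'
#' Mean over all rater pairs of the per-pair fraction of lesions on which
#' the two raters reported the same perceived AI label. With
#' `exclude_uncertain`, lesions where either rater's label is indeterminate
#' are dropped from that pair's denominator (pairs left with no lesion are
#' dropped from the average).
#'
#' @param cohort A validated `cohort` with at least 2 raters.
#' @param exclude_uncertain Drop indeterminate-label lesions per pair.
#' @return The average pairwise agreement proportion.
#' @export
interrater_ai_agreement <- function(cohort, exclude_uncertain = FALSE) {
  stopifnot_cohort(cohort)
  if (cohort$n_raters < 2L) stop("need at least 2 raters", call. = FALSE)
  s2 <- cohort$records[session == "S2"]
  wide <- data.table::dcast(s2, lesion_id ~ rater_id, value.var = "perceived_ai_dx")
  lab <- as.matrix(wide[, -1L])
  raters <- colnames(lab)
  combs <- utils::combn(length(raters), 2L)
  props <- apply(combs, 2L, function(jk) {
    a <- lab[, jk[1]]; b <- lab[, jk[2]]
    if (exclude_uncertain) {
      keep <- is_determinate(a) & is_determinate(b)
      if (!any(keep)) return(NA_real_)
      mean(a[keep] == b[keep])
    } else {
      mean(a == b)
    }
  })
  mean(props, na.rm = TRUE)
}
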
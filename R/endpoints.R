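#' Build the influence endpoint rows
#'
#' For each (rater, lesion) pair the AI reference label is the session-2
#' perceived (or algorithmic) AI diagnosis. The response is agreement of the
#' rater's diagnosis with that label, in both sessions; pairs whose AI label
#' is indeterminate are excluded and logged, because agreement is undefined
#' there. A rater's "Uncertain" diagnosis counts as disagreement. The odds
#' ratio of session 2 vs session 1 agreement is the AI-influence endpoint.
#'
#' @param cohort A validated `cohort`.
#' @param ai_basis `"perceived"` (default): the rater's own reading of the
#'   device output; `"algorithmic"`: the machine-read lesion-level label.
#' @return An `endpoint_rows` object: `rows` (y, session, rater_id,
#'   lesion_id), `exclusions` (named counts), `name`, `ai_basis`.
#' @export
build_influence_rows <- function(cohort, ai_basis = c("perceived", "algorithmic")) {
  ai_basis <- match.arg(ai_basis)
  stopifnot_cohort(cohort)
  pairs <- pair_table(cohort)
  ai <- ai_label_column(pairs, ai_basis)
  det <- is_determinate(ai)
  kept <- pairs[det]
  ai <- ai[det]
  rows <- data.table(
    y = as.integer(c(kept$dx1 == ai, kept$dx2 == ai)),
    session = rep(c(0L, 1L), each = nrow(kept)),
    rater_id = rep(kept$rater_id, 2L),
    lesion_id = rep(kept$lesion_id, 2L),
    expertise = rep(kept$expertise, 2L))
  new_endpoint_rows("influence", rows, ai_basis,
                    exclusions = c(ai_indeterminate = sum(!det)),
                    candidates = nrow(pairs))
}

#' Build accuracy endpoint rows, optionally on an AI-correctness subset
#'
#' The response is correctness of the rater's diagnosis against histology
#' ("Uncertain" counts as incorrect) in both sessions. For
#' `subset = "ai_correct"` / `"ai_wrong"` a pair is kept when the AI label
#' (under `ai_basis`) equals / differs from the lesion histology; pairs with
#' an indeterminate AI label are excluded from both subsets, and both
#' session records of a pair share its membership.
#'
#' @inheritParams build_influence_rows
#' @param subset `"all"`, `"ai_correct"` (effectiveness) or `"ai_wrong"`
#'   (safety).
#' @return An `endpoint_rows` object.
#' @export
build_accuracy_rows <- function(cohort, subset = c("all", "ai_correct", "ai_wrong"),
                                ai_basis = c("perceived", "algorithmic")) {
  subset <- match.arg(subset)
  ai_basis <- match.arg(ai_basis)
  stopifnot_cohort(cohort)
  pairs <- pair_table(cohort)
  exclusions <- c()
  if (subset != "all") {
    ai <- ai_label_column(pairs, ai_basis)
    det <- is_determinate(ai)
    ai_correct <- det & ai == pairs$histology
    keep <- if (subset == "ai_correct") ai_correct else det & !ai_correct
    exclusions <- c(ai_indeterminate = sum(!det),
                    other_subset = sum(det) - sum(keep))
    if (!any(keep)) {
      stop(sprintf("endpoint subset '%s' is empty (%d pairs indeterminate, %d in the other subset)",
                   subset, exclusions[["ai_indeterminate"]], exclusions[["other_subset"]]),
           call. = FALSE)
    }
    pairs <- pairs[keep]
  }
  rows <- data.table(
    y = as.integer(c(pairs$dx1 == pairs$histology, pairs$dx2 == pairs$histology)),
    session = rep(c(0L, 1L), each = nrow(pairs)),
    rater_id = rep(pairs$rater_id, 2L),
    lesion_id = rep(pairs$lesion_id, 2L),
    expertise = rep(pairs$expertise, 2L))
  name <- switch(subset, all = "accuracy", ai_correct = "effectiveness",
                 ai_wrong = "safety")
  new_endpoint_rows(name, rows, ai_basis, exclusions = exclusions,
                    candidates = nrow(pair_table(cohort)))
}

new_endpoint_rows <- function(name, rows, ai_basis, exclusions, candidates) {
  structure(list(name = name, rows = rows, ai_basis = ai_basis,
                 exclusions = exclusions,
                 n_pairs = as.integer(nrow(rows) / 2L), n_candidates = candidates),
            class = "endpoint_rows")
}

#' @export
print.endpoint_rows <- function(x, ...) {
  cat(sprintf("<endpoint_rows> %s (%s AI basis): %d pairs retained of %d candidates\n",
              x$name, x$ai_basis, x$n_pairs, x$n_candidates))
  if (length(x$exclusions)) {
    cat("  exclusions:", paste(sprintf("%s=%d", names(x$exclusions), x$exclusions),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

ENDPOINT_BOUNDS <- c(influence = 1, accuracy = 1, effectiveness = 1, safety = 0.3)

#' Estimate the four pre-registered endpoint odds ratios
#'
#' Fits the crossed random-intercept logistic model to each endpoint row set
#' and attaches 95% Wald intervals and the pre-registered one-sided tests:
#' influence, accuracy and effectiveness against the bound OR > 1, safety
#' against OR > 0.3. With `subgroups = TRUE` each endpoint is additionally
#' estimated on separate fits restricted to experts and to non-experts.
#'
#' @inheritParams build_influence_rows
#' @param settings A [glmm_settings()] list.
#' @param subgroups Also fit expert / non-expert subgroups.
#' @param level Confidence level of the Wald intervals.
#' @return A data.frame of class `"endpoint_estimates"` with one row per
#'   endpoint x subgroup: `endpoint, subgroup, or_value, ci_low, ci_high,
#'   log_or, se, test_bound, p_one_sided, converged, n_pairs`. The fitted
#'   `glmm_fit` objects are attached as the `"fits"` attribute.
#' @export
estimate_endpoints <- function(cohort, ai_basis = c("perceived", "algorithmic"),
                               settings = glmm_settings(), subgroups = TRUE,
                               level = 0.95) {
  ai_basis <- match.arg(ai_basis)
  stopifnot_cohort(cohort)
  row_sets <- list(
    influence = build_influence_rows(cohort, ai_basis),
    accuracy = build_accuracy_rows(cohort, "all", ai_basis),
    effectiveness = build_accuracy_rows(cohort, "ai_correct", ai_basis),
    safety = build_accuracy_rows(cohort, "ai_wrong", ai_basis))
  groups <- if (subgroups) c("all", "expert", "nonexpert") else "all"
  out <- list(); fits <- list()
  for (ep in names(row_sets)) {
    for (g in groups) {
      rows <- row_sets[[ep]]$rows
      if (g == "expert") rows <- rows[expertise == "Expert"]
      if (g == "nonexpert") rows <- rows[expertise == "NonExpert"]
      est <- tryCatch({
        fit <- fit_crossed_logistic(rows, settings)
        ci <- wald_interval(fit, level)
        test <- test_one_sided(fit, ENDPOINT_BOUNDS[[ep]], "greater")
        fits[[paste(ep, g, sep = ".")]] <- fit
        data.frame(endpoint = ep, subgroup = g,
                   or_value = exp(fit$beta[["session"]]),
                   ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
                   log_or = fit$beta[["session"]], se = fit$se_beta[["session"]],
                   test_bound = ENDPOINT_BOUNDS[[ep]], p_one_sided = test$p,
                   converged = fit$converged, n_pairs = nrow(rows) / 2L,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        stop(sprintf("endpoint '%s' (subgroup %s) failed: %s", ep, g, conditionMessage(e)),
             call. = FALSE)
      })
      out[[paste(ep, g, sep = ".")]] <- est
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fits") <- fits
  attr(res, "exclusions") <- lapply(row_sets, function(r) r$exclusions)
  attr(res, "ai_basis") <- ai_basis
  class(res) <- c("endpoint_estimates", "data.frame")
  res
}

#' @export
print.endpoint_estimates <- function(x, ...) {
  cat(sprintf("Endpoint odds ratios (%s AI basis, 95%% Wald CIs)\n", attr(x, "ai_basis")))
  df <- as.data.frame(x)
  df$estimate <- sprintf("%.2f [%.2f, %.2f]", df$or_value, df$ci_low, df$ci_high)
  df$test <- sprintf("OR > %.2g: p = %.2g", df$test_bound, df$p_one_sided)
  print(df[, c("endpoint", "subgroup", "estimate", "test", "n_pairs")], row.names = FALSE)
  invisible(x)
}

#' Reciprocal of the safety odds ratio
#'
#' The safety endpoint is reported as an odds ratio below 1 (accuracy when
#' the AI is wrong); its reciprocal is the "followed incorrect advice" odds
#' ratio quoted alongside effectiveness.
#'
#' @param estimate One row of an `endpoint_estimates` frame (or the frame
#'   itself, from which the overall safety row is taken), or a single OR.
#' @return The reciprocal rounded to 2 decimals.
#' @export
report_reciprocal_safety <- function(estimate) {
  or <- if (is.numeric(estimate)) {
    estimate
  } else {
    df <- as.data.frame(estimate)
    row <- df[df$endpoint == "safety" & df$subgroup == "all", ]
    if (nrow(row) != 1L) stop("expected a safety estimate", call. = FALSE)
    row$or_value
  }
  round(1 / or, 2)
}
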
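#' Run the full analysis pipeline and write a report bundle
#'
#' End-to-end: load or generate a cohort, validate it, estimate the four
#' endpoint odds ratios (with expertise subgroups), compute the calibration
#' and agreement tables, and render everything into an output directory:
#'
#' * `estimates.json` — endpoint estimates with CIs, tests, exclusion logs;
#' * `tables.json` — calibration tables, switch rates, AI accuracies,
#'   agreement statistics;
#' * `report.txt` — aligned-text rendering; every number is taken from the
#'   JSON values, never recomputed;
#' * `exclusions.log` — per-endpoint exclusion counts;
#' * `cohort.csv` — the generated cohort (generator input only).
#'
#' The run is idempotent given the seed and inputs. On failure the stage is
#' named and partial outputs are removed.
#'
#' @param cohort_path Path to a cohort CSV, or `NULL` to generate.
#' @param config A [generator_config()] used when `cohort_path` is `NULL`.
#' @param out_dir Output directory, created if needed.
#' @param ai_basis `"perceived"` or `"algorithmic"`.
#' @param seed Seed recorded in every artifact; overrides `config$seed`.
#' @param settings GLMM settings.
#' @param subgroups Fit expertise subgroups.
#' @return Invisibly, a list with the in-memory `estimates`, `tables`, and
#'   the output paths.
#' @export
run_pipeline <- function(cohort_path = NULL, config = generator_config(),
                         out_dir = "hybriddx_run", ai_basis = "perceived",
                         seed = config$seed, settings = glmm_settings(),
                         subgroups = TRUE) {
  if (!is.null(cohort_path) && !missing(config) && !is.null(config)) {
    stop("supply exactly one input source: a cohort CSV or a generator config",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("estimates.json", "tables.json", "report.txt",
                                "exclusions.log", "cohort.csv"))
  names(paths) <- c("estimates", "tables", "report", "exclusions", "cohort")
  written <- character(0)
  on_fail <- function(stage, e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  stage <- function(name, expr) tryCatch(expr, error = function(e) on_fail(name, e))

  cohort <- stage("load", {
    if (!is.null(cohort_path)) {
      read_cohort_csv(cohort_path)
    } else {
      co <- generate_cohort(config, seed = seed)
      write_cohort_csv(co, paths[["cohort"]])
      written <- c(written, paths[["cohort"]])
      co
    }
  })

  estimates <- stage("endpoints",
                     estimate_endpoints(cohort, ai_basis, settings, subgroups = subgroups))
  tables <- stage("calibration", list(
    accuracy_S1 = accuracy_by_confidence(cohort, "S1"),
    accuracy_S2 = accuracy_by_confidence(cohort, "S2"),
    accuracy_ai = accuracy_by_confidence(cohort, "ai_perceived"),
    switch_by_human_conf = switch_rate_by_confidence(cohort, "human_conf_S1"),
    switch_by_ai_conf = switch_rate_by_confidence(cohort, "ai_conf"),
    ai_accuracy = list(
      perceived_s = ai_accuracy(cohort, "perceived", "s"),
      perceived_u = ai_accuracy(cohort, "perceived", "u"),
      algorithmic_s = ai_accuracy(cohort, "algorithmic", "s"),
      algorithmic_u = ai_accuracy(cohort, "algorithmic", "u")),
    agreement = list(
      perceived_vs_algorithmic = perceived_vs_algorithmic_agreement(cohort, FALSE),
      perceived_vs_algorithmic_det = perceived_vs_algorithmic_agreement(cohort, TRUE),
      interrater = interrater_ai_agreement(cohort, FALSE),
      interrater_det = interrater_ai_agreement(cohort, TRUE))))

  stage("render", {
    write_estimates_json(estimates, paths[["estimates"]], seed = seed)
    written <- c(written, paths[["estimates"]])
    jsonlite::write_json(
      list(seed = seed, tables = serialize_tables(tables)),
      paths[["tables"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, paths[["tables"]])
    writeLines(render_exclusions(estimates), paths[["exclusions"]])
    written <- c(written, paths[["exclusions"]])
    writeLines(render_report(estimates, tables, seed), paths[["report"]])
  })
  invisible(list(estimates = estimates, tables = tables, paths = paths,
                 cohort = cohort))
}

serialize_tables <- function(tables) {
  ser <- function(x) {
    if (inherits(x, "calibration_table")) {
      list(stratifier = x$stratifier, cells = x$cells,
           overall = as.list(x$overall))
    } else if (is.list(x)) lapply(x, ser) else x
  }
  lapply(tables, ser)
}

render_exclusions <- function(estimates) {
  ex <- attr(estimates, "exclusions")
  unlist(lapply(names(ex), function(ep) {
    if (length(ex[[ep]]) == 0L) return(sprintf("%s: no exclusions", ep))
    sprintf("%s: %s", ep,
            paste(sprintf("%s=%d", names(ex[[ep]]), ex[[ep]]), collapse = ", "))
  }))
}

# report.txt mirrors the JSON numbers; formatting only, no recomputation
render_report <- function(estimates, tables, seed) {
  df <- as.data.frame(estimates)
  fmt_est <- function(g) {
    sub <- df[df$subgroup == g, ]
    sprintf("  %-13s %6.2f  [%5.2f, %5.2f]   p(OR > %.2g) = %.3g",
            sub$endpoint, sub$or_value, sub$ci_low, sub$ci_high,
            sub$test_bound, sub$p_one_sided)
  }
  fmt_cal <- function(tab, title) {
    c(sprintf("%s (by %s)", title, tab$stratifier),
      sprintf("  %-9s %6.3f  (n = %d)", tab$cells$level, tab$cells$proportion,
              tab$cells$n),
      sprintf("  %-9s %6.3f  (n = %d)", "overall", tab$overall[["proportion"]],
              as.integer(tab$overall[["n"]])))
  }
  acc <- tables$ai_accuracy
  agr <- tables$agreement
  out <- c(
    sprintf("hybriddx pipeline report (seed = %s)", seed),
    "", "Endpoint odds ratios, all raters (95% Wald CI):", fmt_est("all"))
  if (any(df$subgroup == "expert")) {
    out <- c(out, "", "Experts:", fmt_est("expert"),
             "", "Non-experts:", fmt_est("nonexpert"))
  }
  c(out, "",
    fmt_cal(tables$accuracy_S1, "Accuracy, session 1"), "",
    fmt_cal(tables$accuracy_S2, "Accuracy, session 2"), "",
    fmt_cal(tables$accuracy_ai, "Perceived AI accuracy"), "",
    fmt_cal(tables$switch_by_human_conf, "Switch rate"), "",
    fmt_cal(tables$switch_by_ai_conf, "Switch rate"), "",
    "AI accuracy conventions:",
    sprintf("  perceived   s = %.3f (n = %d)   u = %.3f (n = %d)",
            acc$perceived_s[["proportion"]], as.integer(acc$perceived_s[["n"]]),
            acc$perceived_u[["proportion"]], as.integer(acc$perceived_u[["n"]])),
    sprintf("  algorithmic s = %.3f (n = %d)   u = %.3f (n = %d)",
            acc$algorithmic_s[["proportion"]], as.integer(acc$algorithmic_s[["n"]]),
            acc$algorithmic_u[["proportion"]], as.integer(acc$algorithmic_u[["n"]])),
    "",
    "Agreement on the AI label:",
    sprintf("  perceived vs algorithmic: %.3f (%.3f excluding indeterminate)",
            agr$perceived_vs_algorithmic, agr$perceived_vs_algorithmic_det),
    sprintf("  inter-rater (mean pairwise): %.3f (%.3f excluding indeterminate)",
            agr$interrater, agr$interrater_det))
}
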
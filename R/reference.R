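#' Reported results of the reference multicentre trial
#'
#' The published summary tables of the multicentre paired-session
#' optical-diagnosis trial that this package's analysis pipeline models
#' (21 endoscopists, 10 of them experts; 504 lesions; two sessions). They
#' are inputs for desk-level consistency checks — e.g. reconstructing an
#' overall accuracy from per-confidence cells via [table_overall()] — and
#' for comparing a reanalysis of the deposited data against the reported
#' endpoint estimates. Values are quoted at their printed precision.
#'
#' `endpoints`: odds ratios with 95% CI bounds, overall and by expertise
#' subgroup. `accuracy_by_confidence`: per-confidence accuracy cells for
#' the two rater sessions and the perceived AI, with the printed overall
#' row (the AI row prints an overall n of 9086 while its cells sum to
#' 9087). `switch_rate`: opinion-switch proportions by own and by AI
#' confidence. `ai_accuracy`: the four headline AI accuracy figures (in
#' percent).
#'
#' @return A list of data.frames: `endpoints`, `accuracy_by_confidence`,
#'   `switch_rate`, and the named vector `ai_accuracy`.
#' @export
reference_results <- function() {
  endpoints <- data.frame(
    endpoint = rep(c("influence", "accuracy", "effectiveness", "safety"), 3L),
    subgroup = rep(c("all", "expert", "nonexpert"), each = 4L),
    or_value = c(3.05, 1.39, 3.48, 0.54,
                 2.88, 1.15, 3.22, 0.45,
                 3.20, 1.61, 3.65, 0.63),
    ci_low = c(2.76, 1.28, 3.07, 0.48,
               2.48, 1.01, 2.64, 0.37,
               2.80, 1.44, 3.11, 0.54),
    ci_high = c(3.39, 1.51, 3.98, 0.62,
                3.34, 1.30, 3.93, 0.54,
                3.65, 1.79, 4.28, 0.75),
    stringsAsFactors = FALSE)

  lev <- c("VeryLow", "Low", "High", "VeryHigh")
  accuracy_by_confidence <- data.frame(
    series = rep(c("S1", "S2", "ai_perceived"), each = 4L),
    level = rep(lev, 3L),
    proportion = c(0.644, 0.685, 0.806, 0.853,
                   0.543, 0.679, 0.839, 0.882,
                   0.667, 0.718, 0.863, 0.909),
    n = c(236, 2665, 5263, 2241,
          184, 1859, 5235, 3094,
          216, 1456, 4608, 2807),
    stringsAsFactors = FALSE)
  overall <- data.frame(
    series = c("S1", "S2", "ai_perceived"),
    proportion = c(0.768, 0.802, 0.849),
    n = c(10584, 10584, 9086),
    stringsAsFactors = FALSE)

  switch_rate <- data.frame(
    stratifier = rep(c("human_conf_S1", "ai_conf"), each = 4L),
    level = rep(lev, 2L),
    proportion = c(0.703, 0.738, 0.668, 0.598,
                   0.278, 0.438, 0.827, 0.888),
    n = c(64, 577, 689, 194,
          97, 457, 684, 286),
    stringsAsFactors = FALSE)

  list(endpoints = endpoints,
       accuracy_by_confidence = accuracy_by_confidence,
       accuracy_overall = overall,
       switch_rate = switch_rate,
       ai_accuracy = c(perceived_s = 84.9, perceived_u = 72.9,
                       algorithmic_s = 84.5, algorithmic_u = 79.3),
       n_trials = 21L * 504L,
       n_indeterminate_perceived_per_rater = 71L,
       n_lesions = 504L)
}

#' Re-estimate the reference endpoints from a deposited trial CSV
#'
#' Runs the full endpoint pipeline on the de-identified trial deposit
#' (a long-format cohort CSV as described in [read_cohort_csv()]); the
#' deposit is not distributed with this package and must be downloaded by
#' the user. Intended for comparing a fresh reanalysis against
#' [reference_results()]`$endpoints`.
#'
#' @param path Path to the deposit CSV.
#' @param ... Passed to [estimate_endpoints()].
#' @return An `endpoint_estimates` frame.
#' @export
reproduce_reference_estimates <- function(path, ...) {
  estimate_endpoints(read_cohort_csv(path), ...)
}
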
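#' Simulation-based power for the pre-registered endpoint tests
#'
#' Repeatedly generates cohorts from `config` (with optional field
#' overrides), runs the endpoint pipeline, and records for each endpoint the
#' fraction of replicates whose one-sided Wald test rejects at level
#' `alpha` (influence, accuracy, effectiveness against OR > 1; safety
#' against OR > 0.3). Replicates whose fits do not converge are counted and
#' reported, not dropped: a non-converged endpoint fit counts as a
#' non-rejection.
#'
#' @param config A [generator_config()].
#' @param overrides Named list of config fields to override (effect
#'   manipulations), e.g. `list(weight_ai = c(VeryLow = 0, Low = 0, High = 0,
#'   VeryHigh = 0))` for the no-reliance null.
#' @param n_reps Number of replicates.
#' @param alpha One-sided test level.
#' @param endpoints Which endpoints to simulate (subset of influence,
#'   accuracy, effectiveness, safety); fewer endpoints is faster.
#' @param ai_basis Passed to [estimate_endpoints()].
#' @param settings GLMM settings.
#' @return A list with `rejection_rate` and `mc_se` (named per endpoint),
#'   `n_reps`, `n_nonconverged`, `n_failed` (replicates where an endpoint
#'   could not be estimated at all, e.g. an empty subset), `alpha`.
#' @export
simulate_power <- function(config = generator_config(), overrides = list(),
                           n_reps = 100L, alpha = 0.05,
                           endpoints = c("influence", "accuracy", "effectiveness", "safety"),
                           ai_basis = "perceived", settings = glmm_settings()) {
  stopifnot(n_reps >= 1)
  n_reps <- as.integer(n_reps)
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  cfg <- config
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg <- validate_generator_config(cfg)

  reject <- matrix(NA, n_reps, length(endpoints), dimnames = list(NULL, endpoints))
  nonconv <- stats::setNames(integer(length(endpoints)), endpoints)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    cohort <- generate_cohort(cfg, seed = substream_seed(cfg$seed, "power", r))
    est <- tryCatch(
      estimate_endpoints_subset(cohort, endpoints, ai_basis, settings),
      error = function(e) NULL)
    if (is.null(est)) { n_failed <- n_failed + 1L; next }
    for (ep in endpoints) {
      row <- est[est$endpoint == ep, ]
      if (!row$converged) {
        nonconv[[ep]] <- nonconv[[ep]] + 1L
        reject[r, ep] <- FALSE
      } else {
        reject[r, ep] <- row$p_one_sided < alpha
      }
    }
  }
  rate <- colMeans(reject, na.rm = TRUE)
  m <- colSums(!is.na(reject))
  list(rejection_rate = rate,
       mc_se = sqrt(rate * (1 - rate) / pmax(m, 1)),
       n_reps = n_reps, n_nonconverged = nonconv, n_failed = n_failed,
       alpha = alpha)
}

# estimate only the named endpoints, overall group, no subgroup fits
estimate_endpoints_subset <- function(cohort, endpoints, ai_basis, settings) {
  builders <- list(
    influence = function() build_influence_rows(cohort, ai_basis),
    accuracy = function() build_accuracy_rows(cohort, "all", ai_basis),
    effectiveness = function() build_accuracy_rows(cohort, "ai_correct", ai_basis),
    safety = function() build_accuracy_rows(cohort, "ai_wrong", ai_basis))
  out <- lapply(endpoints, function(ep) {
    fit <- fit_crossed_logistic(builders[[ep]](), settings)
    p <- if (fit$converged) test_one_sided(fit, ENDPOINT_BOUNDS[[ep]], "greater")$p else NA_real_
    data.frame(endpoint = ep, or_value = exp(fit$beta[["session"]]),
               p_one_sided = p, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
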
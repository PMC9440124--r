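#' Configuration of the latent-evidence cohort generator
#'
#' The generator emulates a paired-session optical-diagnosis trial. Each
#' lesion i has a binary histology (sign h_i = +1 for adenoma) and a
#' difficulty d_i ~ N(0, lesion_difficulty_sd). Each rater j has a latent
#' discriminability s_j drawn around the group mean (`expert_skill` /
#' `nonexpert_skill`). A first-session reading is a latent evidence draw
#' x_ij ~ N((s_j - d_i) h_i, 1); its sign gives the diagnosis, evidence
#' magnitude below `uncertain_band_human` gives an uncertain call, and the
#' magnitude binned at `confidence_cutpoints_human` gives the confidence
#' level, so confidence is calibrated by construction. The AI produces
#' e_ai ~ N(ai_skill * h_i, 1), abstaining ("Undetermined") when
#' |e_ai| < ai_indeterminate_threshold; its displayed confidence bins |e_ai|
#' at `confidence_cutpoints_ai`. In session 2 the rater re-reads the lesion
#' (fresh latent draw when `s2_redraw`, the session-1 draw otherwise) and
#' combines it with the perceived AI advice by a confidence-weighted mean
#' (see [integrate_beliefs()]).
#'
#' The default `ai_skill` and `ai_indeterminate_threshold` solve the
#' closed-form identities
#' `Phi(s - tau) / (Phi(s - tau) + Phi(-s - tau)) = 0.849` and
#' `Phi(tau - s) - Phi(-tau - s) = 71/504`, so the simulated device has a
#' determinate accuracy near 85% and abstains on about 14% of lesions.
#'
#' @param n_raters,n_expert Number of raters and how many of them are
#'   experts; by default experts make up the same 10/21 share as in the
#'   reference design.
#' @param n_lesions Number of lesions per session.
#' @param adenoma_prevalence Probability that a lesion is an adenoma. The
#'   source trial does not report its prevalence; 0.6 is a configurable
#'   placeholder.
#' @param lesion_difficulty_sd SD of the lesion difficulty d_i.
#' @param expert_skill,nonexpert_skill Group means of the rater
#'   discriminability s_j.
#' @param rater_skill_sd SD of s_j around its group mean.
#' @param ai_skill Mean AI evidence magnitude s_ai.
#' @param ai_indeterminate_threshold Evidence magnitude below which the AI
#'   abstains (tau_ai).
#' @param misread_prob Probability that a rater misreads a determinate
#'   displayed AI label as the opposite label.
#' @param confidence_cutpoints_human,confidence_cutpoints_ai Strictly
#'   increasing triples on the evidence magnitude separating
#'   VeryLow / Low / High / VeryHigh.
#' @param uncertain_band_human Evidence magnitude below which the human
#'   diagnosis is "Uncertain".
#' @param expert_conf_shift Added to the expert cutpoints: experts report
#'   lower confidence at the same evidence.
#' @param weight_human,weight_ai Positive integration weights per confidence
#'   level (VeryLow, Low, High, VeryHigh), for the rater's own evidence and
#'   for the perceived AI advice.
#' @param ai_advice_scale Evidence magnitude assigned to a determinate
#'   perceived AI label during integration.
#' @param s2_redraw If `TRUE` (default) the session-2 own evidence is an
#'   independent re-reading; if `FALSE` the session-1 latent is reused, so
#'   with zero AI weight session 2 reproduces session 1 exactly.
#' @param seed Integer seed; every sampling step derives from it.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_raters = 21L,
                             n_expert = round(n_raters * 10 / 21),
                             n_lesions = 504L,
                             adenoma_prevalence = 0.6,
                             lesion_difficulty_sd = 0.55,
                             expert_skill = 1.15,
                             nonexpert_skill = 0.75,
                             rater_skill_sd = 0.15,
                             ai_skill = 0.8693364,
                             ai_indeterminate_threshold = 0.2583406,
                             misread_prob = 0.06,
                             confidence_cutpoints_human = c(0.25, 0.8, 2.0),
                             confidence_cutpoints_ai = c(0.45, 0.8, 1.6),
                             uncertain_band_human = 0.1,
                             expert_conf_shift = 0.15,
                             weight_human = c(VeryLow = 0.6, Low = 1.0, High = 1.8, VeryHigh = 2.6),
                             weight_ai = c(VeryLow = 0.25, Low = 0.55, High = 1.1, VeryHigh = 1.6),
                             ai_advice_scale = 1.0,
                             s2_redraw = TRUE,
                             seed = 1L) {
  cfg <- list(n_raters = as.integer(n_raters), n_expert = as.integer(n_expert),
              n_lesions = as.integer(n_lesions),
              adenoma_prevalence = adenoma_prevalence,
              lesion_difficulty_sd = lesion_difficulty_sd,
              expert_skill = expert_skill, nonexpert_skill = nonexpert_skill,
              rater_skill_sd = rater_skill_sd, ai_skill = ai_skill,
              ai_indeterminate_threshold = ai_indeterminate_threshold,
              misread_prob = misread_prob,
              confidence_cutpoints_human = confidence_cutpoints_human,
              confidence_cutpoints_ai = confidence_cutpoints_ai,
              uncertain_band_human = uncertain_band_human,
              expert_conf_shift = expert_conf_shift,
              weight_human = weight_human, weight_ai = weight_ai,
              ai_advice_scale = ai_advice_scale,
              s2_redraw = isTRUE(s2_redraw), seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  chk <- function(ok, msg) if (!all(ok)) stop("invalid generator config: ", msg, call. = FALSE)
  chk(cfg$n_raters >= 1 && cfg$n_lesions >= 1, "counts must be positive")
  chk(cfg$n_expert >= 0 && cfg$n_expert <= cfg$n_raters,
      "n_expert must be between 0 and n_raters")
  probs <- c(cfg$adenoma_prevalence, cfg$misread_prob)
  chk(probs >= 0 & probs <= 1, "probabilities must lie in [0, 1]")
  chk(c(cfg$lesion_difficulty_sd, cfg$rater_skill_sd) >= 0, "SDs must be non-negative")
  chk(c(cfg$expert_skill, cfg$nonexpert_skill, cfg$ai_skill) >= 0,
      "skills must be non-negative")
  chk(cfg$ai_indeterminate_threshold >= 0 && cfg$uncertain_band_human >= 0,
      "thresholds must be non-negative")
  for (cp in list(cfg$confidence_cutpoints_human, cfg$confidence_cutpoints_ai)) {
    chk(length(cp) == 3L && all(diff(cp) > 0), "cutpoint triples must be strictly increasing")
  }
  for (w in list(cfg$weight_human, cfg$weight_ai)) {
    chk(length(w) == 4L && all(w >= 0) &&
          identical(names(w), CONFIDENCE_DET_LEVELS),
        "weights must be non-negative and named VeryLow, Low, High, VeryHigh")
  }
  chk(cfg$ai_advice_scale > 0, "ai_advice_scale must be positive")
  cfg
}

# bin an evidence magnitude into the four confidence levels
bin_confidence <- function(magnitude, cutpoints) {
  CONFIDENCE_DET_LEVELS[findInterval(magnitude, cutpoints) + 1L]
}

histology_sign <- function(histology) ifelse(histology == "Adenoma", 1, -1)
sign_to_label <- function(s) ifelse(s > 0, "Adenoma", "NonAdenoma")

#' Simulate the AI output for a set of lesions
#'
#' Draws latent AI evidence e_ai ~ N(s_ai * h, 1), abstains below the
#' indeterminate threshold, and bins |e_ai| into a displayed confidence.
#'
#' @param histology Character vector of binary histologies.
#' @param config A [generator_config()].
#' @return A data.frame with columns `algorithmic_ai_dx`, `displayed_ai_conf`
#'   (NA when undetermined) and the latent `e_ai`.
#' @export
simulate_ai <- function(histology, config) {
  assert_levels(histology, HISTOLOGY_LEVELS, "histology")
  e_ai <- stats::rnorm(length(histology), config$ai_skill * histology_sign(histology), 1)
  det <- abs(e_ai) >= config$ai_indeterminate_threshold
  data.frame(
    algorithmic_ai_dx = ifelse(det, sign_to_label(e_ai), "Undetermined"),
    displayed_ai_conf = ifelse(det, bin_confidence(abs(e_ai), config$confidence_cutpoints_ai),
                               NA_character_),
    e_ai = e_ai, stringsAsFactors = FALSE)
}

#' Simulate an unassisted (session-1 style) reading
#'
#' @param skill Rater discriminability s_j (vectorized).
#' @param difficulty Lesion difficulty d_i (vectorized).
#' @param histology Binary histology vector.
#' @param config A [generator_config()].
#' @param conf_shift Added to the confidence cutpoints (expert shift).
#' @return A data.frame with `diagnosis`, `confidence` and the latent `x`.
#' @export
simulate_s1 <- function(skill, difficulty, histology, config, conf_shift = 0) {
  x <- stats::rnorm(length(histology), (skill - difficulty) * histology_sign(histology), 1)
  classify_evidence(x, config, conf_shift)
}

# shared evidence -> (diagnosis, confidence) binning used by both sessions;
# a positive conf_shift raises the cutpoints, i.e. lowers reported confidence
classify_evidence <- function(x, config, conf_shift = 0) {
  unc <- abs(x) < config$uncertain_band_human
  data.frame(
    diagnosis = ifelse(unc, "Uncertain", sign_to_label(x)),
    confidence = ifelse(unc, "Uncertain",
                        bin_confidence(abs(x) - conf_shift,
                                       config$confidence_cutpoints_human)),
    x = x, stringsAsFactors = FALSE)
}

#' Confidence-weighted integration of own evidence and AI advice
#'
#' The session-2 latent is the weighted mean
#' `z = (w_h(conf) * x + w_ai(ai_conf) * a) / (w_h(conf) + w_ai(ai_conf))`
#' where `a` is `+ai_advice_scale` for a perceived "Adenoma",
#' `-ai_advice_scale` for "NonAdenoma" and `0` (with zero AI weight) for an
#' indeterminate perceived label. Normalising by the total weight keeps z on
#' the evidence scale of x, so the session-1 cutpoints apply unchanged; in
#' particular with `w_ai == 0` the session-2 diagnosis and confidence equal
#' the session-1 ones exactly, and with `w_h == 0` and a determinate label
#' the diagnosis equals the perceived AI label.
#'
#' @param x Own latent evidence (vectorized).
#' @param human_conf Confidence level attached to `x` ("Uncertain" allowed;
#'   uncertain readings carry the smallest determinate weight).
#' @param perceived_ai_dx Perceived AI label.
#' @param perceived_ai_conf Perceived AI confidence (NA when the label is
#'   indeterminate).
#' @param config A [generator_config()].
#' @return A data.frame with `diagnosis`, `confidence` and the latent `z`.
#' @export
integrate_beliefs <- function(x, human_conf, perceived_ai_dx, perceived_ai_conf, config) {
  w_h <- ifelse(human_conf == "Uncertain",
                config$weight_human[["VeryLow"]],
                config$weight_human[human_conf])
  det <- is_determinate(perceived_ai_dx)
  a <- ifelse(det, ifelse(perceived_ai_dx == "Adenoma", 1, -1) * config$ai_advice_scale, 0)
  w_ai <- ifelse(det, config$weight_ai[ifelse(det, perceived_ai_conf, "VeryLow")], 0)
  tot <- w_h + w_ai
  z <- ifelse(tot > 0, (w_h * x + w_ai * a) / pmax(tot, .Machine$double.eps), 0)
  out <- classify_evidence(z, config)
  names(out)[names(out) == "x"] <- "z"
  out
}

#' Generate a full two-session synthetic cohort
#'
#' Deterministic given `config$seed` (or the `seed` override): produces
#' `2 * n_raters * n_lesions` records satisfying every cohort invariant.
#' Perceived AI labels equal the displayed ones except for symmetric label
#' misreads (probability `misread_prob`); displayed "Undetermined" is
#' perceived as "Uncertain" or "NotNoticed".
#'
#' @param config A [generator_config()].
#' @param seed Optional seed override.
#' @return A validated `cohort` object.
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL) {
  config <- validate_generator_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  withr_seed(config$seed, {
    nr <- config$n_raters; nl <- config$n_lesions
    rater_id <- sprintf("R%02d", seq_len(nr))
    expertise <- rep(c("Expert", "NonExpert"), c(config$n_expert, nr - config$n_expert))
    skill_mean <- ifelse(expertise == "Expert", config$expert_skill, config$nonexpert_skill)
    skill <- pmax(stats::rnorm(nr, skill_mean, config$rater_skill_sd), 0)
    conf_shift <- ifelse(expertise == "Expert", config$expert_conf_shift, 0)

    lesion_id <- sprintf("L%04d", seq_len(nl))
    histology <- ifelse(stats::runif(nl) < config$adenoma_prevalence, "Adenoma", "NonAdenoma")
    difficulty <- stats::rnorm(nl, 0, config$lesion_difficulty_sd)
    ai <- simulate_ai(histology, config)

    # long index: rater varies slowest
    ridx <- rep(seq_len(nr), each = nl)
    lidx <- rep(seq_len(nl), times = nr)
    n <- nr * nl

    s1 <- simulate_s1(skill[ridx], difficulty[lidx], histology[lidx], config,
                      conf_shift[ridx])

    # perceived AI label: per rater x lesion, misreads flip determinate labels
    disp <- ai$algorithmic_ai_dx[lidx]
    det <- is_determinate(disp)
    flip <- det & stats::runif(n) < config$misread_prob
    perceived <- disp
    perceived[flip] <- ifelse(disp[flip] == "Adenoma", "NonAdenoma", "Adenoma")
    u_ind <- stats::runif(n)
    perceived[!det] <- ifelse(u_ind[!det] < 2 / 3, "Uncertain", "NotNoticed")
    perceived_conf <- ifelse(is_determinate(perceived),
                             ai$displayed_ai_conf[lidx], NA_character_)
    # a flipped reading of an abstaining device never happens here, but a
    # determinate misread keeps the displayed confidence

    x2 <- if (config$s2_redraw) {
      stats::rnorm(n, (skill[ridx] - difficulty[lidx]) * histology_sign(histology[lidx]), 1)
    } else s1$x
    conf2_own <- classify_evidence(x2, config, conf_shift[ridx])$confidence
    s2 <- integrate_beliefs(x2, conf2_own, perceived, perceived_conf, config)
    # re-apply the expert confidence shift to the integrated evidence
    s2_conf <- ifelse(s2$diagnosis == "Uncertain", "Uncertain",
                      bin_confidence(abs(s2$z) - conf_shift[ridx],
                                     config$confidence_cutpoints_human))

    rec <- data.table(
      rater_id = rep(rater_id[ridx], 2L),
      lesion_id = rep(lesion_id[lidx], 2L),
      session = rep(c("S1", "S2"), each = n),
      raw_choice = NA_character_,
      diagnosis = c(s1$diagnosis, s2$diagnosis),
      confidence = c(s1$confidence, s2_conf),
      perceived_ai_dx = c(rep(NA_character_, n), perceived),
      perceived_ai_conf = c(rep(NA_character_, n), perceived_conf),
      algorithmic_ai_dx = rep(ai$algorithmic_ai_dx[lidx], 2L),
      histology = rep(histology[lidx], 2L),
      expertise = rep(expertise[ridx], 2L))
    validate_cohort(rec)
  })
}

# evaluate expr with a temporary RNG state seeded at `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic substream seeds below 2^31, derived from a master seed
substream_seed <- function(seed, stream, rep = 0L) {
  offsets <- c(generator = 11L, power = 23L, recovery = 37L, acceptance = 53L)
  off <- if (stream %in% names(offsets)) offsets[[stream]] else 71L
  (as.integer(seed) * 1009L + off * 9973L + as.integer(rep) * 7919L) %% 2147483587L
}
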
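# Build a long-format record set from a per-pair specification. `pairs` is a
# data.frame with columns rater, lesion, dx1, conf1, dx2, conf2, perceived,
# perceived_conf, algorithmic, histology, expertise; missing columns get
# defaults consistent with the cohort invariants.
records_from_pairs <- function(pairs) {
  d <- as.data.frame(pairs, stringsAsFactors = FALSE)
  n <- nrow(d)
  dflt <- function(col, value) {
    if (!is.null(d[[col]])) return(d[[col]])
    if (length(value) == n) value else rep(value, length.out = n)
  }
  d$conf1 <- dflt("conf1", "High")
  d$conf2 <- dflt("conf2", "High")
  d$conf1[d$dx1 == "Uncertain"] <- "Uncertain"
  d$conf2[d$dx2 == "Uncertain"] <- "Uncertain"
  d$perceived <- dflt("perceived", "Adenoma")
  d$perceived_conf <- dflt("perceived_conf", "High")
  d$perceived_conf[!(d$perceived %in% c("Adenoma", "NonAdenoma"))] <- NA
  d$algorithmic <- dflt("algorithmic", d$perceived)
  d$algorithmic[!(d$algorithmic %in% c("Adenoma", "NonAdenoma"))] <- "Undetermined"
  d$histology <- dflt("histology", "Adenoma")
  d$expertise <- dflt("expertise", "Expert")
  data.frame(
    rater_id = rep(as.character(d$rater), 2L),
    lesion_id = rep(as.character(d$lesion), 2L),
    session = rep(c("S1", "S2"), each = n),
    raw_choice = NA_character_,
    diagnosis = c(d$dx1, d$dx2),
    confidence = c(d$conf1, d$conf2),
    perceived_ai_dx = c(rep(NA_character_, n), d$perceived),
    perceived_ai_conf = c(rep(NA_character_, n), d$perceived_conf),
    algorithmic_ai_dx = rep(d$algorithmic, 2L),
    histology = rep(d$histology, 2L),
    expertise = rep(d$expertise, 2L),
    stringsAsFactors = FALSE)
}

cohort_from_pairs <- function(pairs) validate_cohort(records_from_pairs(pairs))

# a small but structurally rich valid cohort: 2 raters x 3 lesions
toy_cohort <- function() {
  cohort_from_pairs(data.frame(
    rater = rep(c("a", "b"), each = 3),
    lesion = rep(c("l1", "l2", "l3"), 2),
    dx1 = c("Adenoma", "NonAdenoma", "Uncertain", "Adenoma", "Adenoma", "NonAdenoma"),
    dx2 = c("Adenoma", "Adenoma", "Adenoma", "NonAdenoma", "Adenoma", "NonAdenoma"),
    perceived = c("Adenoma", "Adenoma", "NonAdenoma", "Uncertain", "Adenoma", "NonAdenoma"),
    algorithmic = rep(c("Adenoma", "Adenoma", "NonAdenoma"), 2),
    histology = rep(c("Adenoma", "NonAdenoma", "NonAdenoma"), 2),
    expertise = rep(c("Expert", "NonExpert"), each = 3)))
}

# fast default: a small synthetic cohort for property tests
small_cohort <- function(seed = 42, n_raters = 4, n_lesions = 40, ...) {
  generate_cohort(generator_config(n_raters = n_raters, n_lesions = n_lesions,
                                   seed = seed, ...))
}

zero_ai_weights <- c(VeryLow = 0, Low = 0, High = 0, VeryHigh = 0)
zero_human_weights <- zero_ai_weights
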
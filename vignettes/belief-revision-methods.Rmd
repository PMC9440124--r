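---
title: "Modelling belief revision in human-AI diagnostic teams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling belief revision in human-AI diagnostic teams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybriddx)
```

## The problem

When an endoscopist reviews a colorectal lesion with a computer-aided
diagnosis (CADx) device, the device's optical diagnosis is one more piece of
evidence to be folded into the clinician's own belief. Whether that folding
is done well determines whether the human-AI team outperforms either member
alone: an under-reliant rater ignores the advice, an over-reliant rater
rubber-stamps it, and a well-calibrated rater weighs it by its case-by-case
reliability. `hybriddx` implements the statistical machinery for analysing
this process in a paired-session design: the same raters diagnose the same
lesions twice, first unassisted (session 1, "S1") and then with the AI
advice visible (session 2, "S2").

## Endpoints and model

Four pre-registered endpoints compare the two sessions, each as an odds
ratio for a binary per-trial outcome:

* **influence** (`or > 1` hypothesised): agreement of the rater's diagnosis
  with the AI label, S2 vs S1 — did opinions converge on the AI?
* **diagnostic accuracy** (`or > 1`): correctness against histology, S2 vs S1;
* **effectiveness** (`or > 1`): the same accuracy contrast restricted to
  trials where the AI was right;
* **safety** (`or > 0.3`): restricted to trials where the AI was wrong. An
  odds ratio below 1 here is expected (bad advice hurts); the pre-registered
  bound asserts the damage is limited.

Every trial is a (rater, lesion, session) observation, and both raters and
lesions are crossed grouping factors, so each endpoint is estimated with a
crossed random-intercept logistic regression

$$\operatorname{logit} P(y_{ij s} = 1) = \beta_0 + \beta_1 s + u_j + v_i,
\qquad u_j \sim N(0, \sigma_r^2),\; v_i \sim N(0, \sigma_\ell^2),$$

where $s \in \{0, 1\}$ indexes the session; $e^{\beta_1}$ is the endpoint
odds ratio. Tests are one-sided Wald tests of $\beta_1$ against the log of
the pre-registered bound; intervals are 95% Wald intervals.

### Fitting

Crossed random effects do not factorise, so adaptive per-group quadrature is
unavailable; the marginal likelihood is approximated by a Laplace expansion
at the mode of the random effects (the approach of the standard
mixed-model packages). The implementation is self-contained:

1. an inner penalized IRLS solve finds the joint mode of $(\beta, u, v)$ for
   fixed variance components; because the lesion block of the penalized
   Hessian is diagonal, each Newton step and the Laplace log-determinant are
   computed by block elimination, reducing every solve to a dense system of
   size `2 + n_raters`;
2. a bounded Nelder-Mead search optimises the two log-SDs (parameterised on
   the log scale with a floor at $e^{-12}$; estimates at the floor are
   reported as $\sigma = 0$ with a boundary flag);
3. because step 1 profiles $\beta$ against the *penalized* objective rather
   than the Laplace objective, a final simplex refinement re-optimises
   $(\beta, \log\sigma_r, \log\sigma_\ell)$ against the Laplace marginal
   likelihood itself. Without this refinement the fixed effect is biased by
   more than the acceptance tolerance on small heterogeneous instances;
   with it the engine agrees with dense Gauss-Hermite product quadrature to
   well under 0.05 on $\beta$. When both SDs are at zero the refinement is
   skipped: the model is then plain logistic regression and the inner solve
   is already exact ML.

Standard errors come from the Schur complement of the joint penalized
Hessian (equivalently, the fixed-effect block of the approximate
observed-information inverse), conditioning on the variance components as
the standard packages do. Degenerate inputs are refused: an all-0 or all-1
response raises a separation error rather than returning an infinite
estimate; non-convergence is flagged and interval/test functions refuse
non-converged fits.

Default tolerances: `1e-6` (outer, log-likelihood scale), `1e-8` (inner,
penalized deviance), 200 outer iterations. All overridable through
`glmm_settings()`. The heavy parameter-recovery acceptance test loosens the
outer tolerance to `1e-5`, which perturbs $\beta$ by about $10^{-3}$ —
negligible against its 0.05 bias tolerance — and keeps 200 full-size
replicates inside the suite's time budget.

### Open analysis choices

Where the published description of the reference trial is ambiguous, the
package makes the following choices, all configurable:

* **Wald intervals** (the alternative, profile intervals, is not stated
  either); a small discrepancy against reported CIs is possible.
* **AI basis**: endpoint subsets and agreement default to the *perceived*
  AI label (what the rater read off the device) rather than the
  *algorithmic* one, because the endpoints concern the advice the rater
  actually received; `ai_basis = "algorithmic"` switches.
* **Indeterminate AI labels** (uncertain / not noticed / undetermined) make
  agreement undefined, so influence pairs with such labels are excluded
  (not scored as disagreement) and counted in the exclusion log;
  effectiveness/safety subsets likewise exclude them, following the
  standard-accuracy convention.
* **Uncertain human diagnoses** count as disagreement in influence and as
  incorrect in all accuracy computations: ground truth is binary, and the
  reported overall-accuracy marginals are reproducible only under this
  convention.
* **Expertise subgroups** are separate fits per group, not an interaction
  model, matching the "estimated separately" wording.
* The 1-9 belief score assigns Adenoma x (VeryLow..VeryHigh) to 6..9 and
  mirrors NonAdenoma onto 4..1 — the only order-preserving symmetric
  assignment consistent with the published endpoints (9 = strong adenoma,
  5 = uncertain, 1 = strong non-adenoma).

## The synthetic cohort generator

The generator exists so that every stage of the pipeline is testable
without access to trial data. It is a latent-evidence (probit-style) model
chosen because it produces, with very few parameters, the two phenomena the
analysis relies on: confidence that predicts accuracy, and
confidence-weighted opinion switching.

* Lesion $i$ has binary histology (sign $h_i = \pm 1$, adenoma prevalence
  0.6 by default — the true prevalence is unpublished, so this is an
  explicit placeholder) and difficulty $d_i \sim N(0, 0.55)$.
* Rater $j$ has discriminability $s_j$ drawn around a group mean (1.15
  experts, 0.75 non-experts, SD 0.15). An unassisted reading is
  $x_{ij} \sim N((s_j - d_i) h_i, 1)$: the sign gives the diagnosis, a
  magnitude below 0.1 gives "Uncertain", and the magnitude binned at
  (0.25, 0.8, 2.0) gives the confidence level. Experts report confidence
  against cutpoints shifted up by 0.15 (same evidence, less confidence).
  Calibration is automatic: larger $|x|$ means both higher confidence and
  higher probability of a correct sign.
* The AI draws $e_i \sim N(s_{ai} h_i, 1)$ and abstains ("Undetermined")
  when $|e_i| < \tau_{ai}$. The defaults $s_{ai} = 0.8693$,
  $\tau_{ai} = 0.2583$ are the exact solution of
  $\Phi(s-\tau)/(\Phi(s-\tau) + \Phi(-s-\tau)) = 0.849$ and
  $\Phi(\tau-s) - \Phi(-\tau-s) = 71/504$: the simulated device has the
  published standard accuracy and abstention rate by construction, and the
  simulator is tested against these closed forms.
* Raters misread a determinate displayed label as its opposite with
  probability 0.06, reproducing the reported ~94% determinate agreement
  between perceived and machine-read labels; a displayed abstention is
  perceived as "Uncertain" (2/3) or "NotNoticed" (1/3).
* In session 2 the rater re-reads the lesion — a fresh draw $x'_{ij}$ by
  default (`s2_redraw = TRUE`), since the sessions are weeks apart — and
  combines it with the advice by a confidence-weighted mean
  $$z_{ij} = \frac{w_h(c_{ij})\, x'_{ij} + w_{ai}(c^{ai}_{ij})\, a_{ij}}
                  {w_h(c_{ij}) + w_{ai}(c^{ai}_{ij})},$$
  where $a_{ij} = \pm 1$ per the perceived label (0, with zero weight, when
  indeterminate). Normalising by the total weight keeps $z$ on the evidence
  scale of $x$, so the session-1 binning rules apply unchanged; it also
  makes the two degenerate regimes exact: zero AI weight reproduces the
  unassisted classification (under-reliance), zero human weight follows any
  determinate advice (over-reliance). With `s2_redraw = FALSE` and zero AI
  weight, session 2 equals session 1 record for record.
* Default weights ($w_h$ = 0.6/1.0/1.8/2.6, $w_{ai}$ = 0.25/0.55/1.1/1.6
  across VeryLow..VeryHigh) were calibrated once, before the tests were
  frozen, so that the full pipeline on default cohorts lands in the
  reported regime (influence OR around 3, effectiveness well above safety);
  they were not revisited afterwards.

What the generator does *not* emulate: frame-by-frame dynamics of the
device overlay (summarised into one label plus a confidence), reaction
times, batch/order effects, rater drift between sessions, and any
systematic miscalibration of confidence. A green test on synthetic data
therefore establishes that the pipeline measures what the generative model
encodes — not that real raters behave this way.

## Power

`simulate_power()` re-derives the design's power by brute force: generate a
cohort under a configuration (optionally with effect overrides), run the
endpoint pipeline, record which one-sided tests reject, repeat. Non-converged
fits count as non-rejections and are reported, not dropped. The type-I-error
property of the accuracy test is verified at a reduced cohort size (8 x 60)
because the null is size-free and 500 full-size null replicates would
dominate the suite budget.

## Known limitations

* Wald (not profile) intervals; slight anti-conservatism is possible when a
  variance component sits near zero.
* The Laplace approximation is known to bias variance components downward
  for sparse binary data; the acceptance suite bounds the induced error on
  the session effect (quadrature agreement, parameter recovery, CI
  coverage) but does not correct it.
* The engine is deliberately narrow: binomial-logit, exactly two crossed
  intercepts, one binary fixed covariate besides the intercept.
* Reported confidence levels enter the integration model only through four
  discrete weights; a continuous-confidence variant is out of scope.
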
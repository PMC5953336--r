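---
title: "Stepwise latent transition model building with ltabuild"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise latent transition model building with ltabuild}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ltabuild` implements a disciplined, stepwise workflow for building latent
transition models for multi-wave categorical questionnaire panels: screen
class counts cross-sectionally, test measurement invariance, select the
number of latent statuses longitudinally, constrain the transition
structure, and add covariates — each step a formal comparison, each
decision logged. This vignette documents the model, the workflow, and the
numerical and design choices that a user of the package should know about.

## The model

Respondent $i$ answers $J$ categorical items (item $j$ has $C_j$
categories) at each of $T$ occasions. The model posits $S$ latent
statuses whose evolution is a first-order Markov chain:

* $\delta_s$ — probability of being in status $s$ at the first occasion;
* $\tau^{(t)}_{rs}$ — probability of moving from status $r$ at occasion
  $t$ to status $s$ at occasion $t+1$;
* $\rho_{s,j,c}$ — probability that a respondent in status $s$ answers
  category $c$ on item $j$ (optionally occasion-specific when
  measurement invariance is relaxed).

Responses are conditionally independent given the status sequence, so a
joint response pattern $y$ has probability

$$P(y) = \sum_{s_1, \dots, s_T} \delta_{s_1} \prod_{t=2}^{T}
  \tau^{(t-1)}_{s_{t-1} s_t} \prod_{t=1}^{T} \prod_{j=1}^{J}
  \rho^{(t)}_{s_t, j, y_{tj}}.$$

With $T = 1$ this reduces to an ordinary latent class model
(`fit_lca()`); `fit_lta()` handles $T \ge 2$. Missing cells (single
items or entire dropped waves) simply contribute no emission factor, the
full-information treatment that is consistent when missingness is
ignorable. Attrition is therefore retained in the panel, never
listwise-deleted.

## Estimation

Estimation is maximum likelihood by EM. The E-step runs a
forward–backward recursion over the latent chain per distinct observed
pattern (patterns are tabulated first, so cost scales with distinct
patterns, not respondents), with per-occasion rescaling to avoid
underflow. The M-step updates $\delta$, $\tau$ and $\rho$ in closed form
from expected counts. Choices worth knowing:

* **Multi-start.** Each fit runs `starts` independent EM runs from
  random initial values (Dirichlet-style draws) and keeps the best
  converged log-likelihood. The convergence report records how many
  starts reached the best value; a warning flags a best value reached by
  only one start, the usual symptom of a multimodal likelihood and an
  under-replicated search.
* **Probability clamping.** All estimated probabilities are clamped to
  $[10^{-6}, 1 - 10^{-6}]$ and renormalized each M-step. This keeps
  log-likelihood contributions finite when a category's expected count
  hits zero, at the cost of a floor on how extreme an estimated
  probability can be.
* **Convergence** is declared when the relative change in
  log-likelihood falls below `tol` (default $10^{-8}$). The
  per-iteration log-likelihood trace is kept on the fit (`ll_trace`);
  EM guarantees it is non-decreasing, and the tests assert this.
* **Label switching.** Latent statuses are only identified up to
  permutation. Fits are reported with statuses ordered by decreasing
  first-occasion prevalence; `align_statuses()` finds the
  item-response-probability permutation closest to a reference, which
  the simulation tests use to compare estimates against a generating
  truth.

## Fit assessment

`gsquared()` compares a fit against the saturated multinomial model on
the observed pattern table. Two design decisions matter here:

* **Missing-data patterns stratify the saturated reference.** With item-
  or wave-level missingness, patterns live in different marginal tables.
  The saturated log-likelihood is computed within strata defined by the
  missingness mask, so the reference always dominates the fitted model
  and $G^2 \ge 0$.
* **Covariate models are conditional.** A model with prevalence
  covariates maximizes a likelihood conditional on $x$, which can
  legitimately exceed the $x$-marginal saturated reference; for such
  fits $G^2$ is reported against the same reference without a
  non-negativity expectation. Differences between nested covariate fits
  remain valid because the common reference cancels. Respondents with
  missing covariate values are excluded from the covariate model *and*
  from its reference table, so both describe the same sample.

`information_criteria()` reports AIC, BIC, CAIC and ABIC as penalized
$G^2$; `residual_df()` counts cells minus parameters minus one, with
parameter counts derived from the spec's invariance and constraint
structure. `relative_entropy()` summarizes classification certainty (it
is reported for context, never used as a fit criterion). `lrdt()` is the
likelihood-ratio difference test for nested pairs.

## The stepwise workflow

`run_framework()` chains the steps; each is also callable on its own.

0. **Candidate pool** (`step0_candidate_pool()`): fit LCAs at every
   occasion over a class-count range; a count enters the pool when it
   minimizes at least one admitted criterion at at least one occasion.
   Manual `include`/`exclude` overrides are honored and logged.
1. **Measurement invariance** (`step1_invariance()`): for each pooled
   count, test occasion-invariant against occasion-free item-response
   probabilities by `lrdt()`. Counts whose invariant model is rejected
   are flagged; invariance is retained when not rejected.
2. **Status-count selection** (`step2_select_statuses()`): compare the
   surviving longitudinal models on the selection criterion (AIC by
   default), then label the selected statuses from their response
   profiles (`status_profile()`), with high-probability entries
   highlighted above a threshold.
3. **Transition structure** (`step3_transition_structure()`): test
   transition invariance over time (shared $\tau$) against free
   occasion-specific matrices.
4. **Covariates** (`step4_covariates()`): add prevalence covariates by a
   one-step (simultaneous) multinomial-logit submodel and test their
   contribution with `covariate_effect_test()`; effects are reported as
   odds ratios against the reference status. Transition covariates are
   available behind a sparseness guard: if any expected
   origin-to-destination count falls below a threshold, estimation
   aborts with an informative error rather than returning unstable
   logits.

The one-step covariate estimator refits a weighted multinomial logit
(hand-rolled Newton iterations with step-halving) inside each M-step;
when the `nnet` package is available the test suite cross-checks it
against `nnet::multinom`. Warm-starting from the covariate-free fit
(slopes at zero) replaces the random multi-start search and is both
faster and the recommended practice, since the covariate-free fit is
always available from the preceding step.

```{r, eval = FALSE}
library(ltabuild)
truth <- bullying_truth(S = 4L)        # built-in generating truth
panel <- simulate_panel(truth, N = 1180L, seed = 1)$panel
report <- run_framework(panel, framework_config(class_range = 2:5,
                                                seed = 1))
report$step2$selection$selected        # chosen status count
write_report(report, "report")         # report.json + report.md
```

## The synthetic generator

`lta_truth()` declares a generating truth (statuses, item-response
probabilities, prevalences, transition matrices, optional prevalence
covariate, monotone attrition schedule, item-level missingness) and
`simulate_panel()` draws panels from it. The generator's parameters are
study conditions: recovery and error-rate properties are measured at
stated designs, not tuned. `bullying_truth()` is a built-in truth shaped
like a three-wave school survey of six binary bullying-concern items
with four statuses (unconcerned through globally concerned) and a
realistic attrition profile; its three-status variant merges the two
moderate-concern statuses, prevalence-weighted, mirroring how central
profiles coalesce when one fewer status is extracted.

## Scope and limitations

* Items must share the same category counts across occasions; the panel
  is a rectangular respondent × occasion × item array.
* The latent chain is first-order; higher-order dependence and
  random-effect extensions are out of scope.
* Standard errors are not reported; inference is by likelihood-ratio
  difference tests between explicitly fitted nested models. (The
  bootstrap would be the natural addition.)
* The missing-data treatment assumes ignorable missingness; informative
  dropout would bias prevalence and transition estimates.
* Step 5 of the workflow (distal outcomes) is recorded in reports as not
  implemented.
* The $10^{-6}$ probability clamp means a generating probability of
  exactly 0 or 1 is estimated as nearly, not exactly, boundary.
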
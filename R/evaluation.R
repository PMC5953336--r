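#' Count free parameters of an LCA/LTA specification
#'
#' The parameter count P drives the residual degrees of freedom
#' `df = W - P - 1` and the information-criterion penalties.  Its pieces:
#' rho contributes `S * sum(C_j - 1)` per distinct occasion set (one set
#' under measurement invariance, T sets otherwise), minus reductions from
#' equality or fixed-value restrictions; the first-occasion prevalence
#' contributes `S - 1` per delta group, or `(S - 1) * (1 + K)` logit
#' coefficients with K prevalence covariates; each distinct transition
#' matrix contributes `S * (S - 1)` (times `1 + K` when covariates act on
#' transitions).
#'
#' @param spec an [lta_spec()].
#' @param n_categories categories per item (scalar or length-J vector);
#'   give the item count through the vector length or `n_items`.
#' @param n_occasions number of occasions T (1 for cross-sectional LCA).
#' @param n_items number of items J (defaults to `length(n_categories)`).
#' @param n_groups number of groups in a multiple-group model.
#' @return Integer parameter count P.
#' @export
count_parameters <- function(spec, n_categories, n_occasions,
                             n_items = length(n_categories), n_groups = 1L) {
  n_categories <- rep_len(as.integer(n_categories), n_items)
  S <- spec$S
  t_occ <- as.integer(n_occasions)
  n_rho_sets <- if (spec$measurement_invariance || t_occ == 1L) 1L else t_occ
  p_rho <- S * sum(n_categories - 1L) * n_rho_sets
  if (!is.null(spec$rho_constraints)) {
    for (g in spec$rho_constraints) {
      cells <- g$cells
      cj <- n_categories[cells$item]
      if (length(unique(cj)) > 1L && is.null(g$fixed))
        stop("equality-constrained cells must share a category count")
      if (is.null(g$fixed)) {
        # m tied category slices estimate one distribution instead of m
        p_rho <- p_rho - (nrow(cells) - 1L) * (cj[1L] - 1L)
      } else {
        p_rho <- p_rho - sum(cj - 1L)
      }
    }
  }
  k <- length(spec$covariates)
  delta_groups <- if (!is.null(spec$group) && spec$group$delta_varies)
    n_groups else 1L
  p_delta <- if (k > 0L) (S - 1L) * (1L + k) * delta_groups
             else (S - 1L) * delta_groups
  n_tau_mats <- if (t_occ <= 1L) 0L
                else if (spec$transition_invariance) 1L else t_occ - 1L
  tau_groups <- if (!is.null(spec$group) && spec$group$tau_varies)
    n_groups else 1L
  per_mat <- S * (S - 1L)
  if (k > 0L && spec$covariate_on_transitions) per_mat <- per_mat * (1L + k)
  p_tau <- per_mat * n_tau_mats * tau_groups
  as.integer(p_rho + p_delta + p_tau)
}

#' Residual degrees of freedom
#'
#' `df = W - P - 1`, where W is the number of possible complete response
#' cells, `prod(C_j)^T`.  A positive df is necessary but not sufficient
#' for identification: when the ratio of observed data to parameters is
#' small the model can still be under-identified, which is why the fit
#' functions warn when `N / P < 5`.
#'
#' @inheritParams count_parameters
#' @param W optionally override the cell count (otherwise computed from
#'   `n_categories` and `n_occasions`).
#' @return Residual degrees of freedom (double: W can exceed integer
#'   range).  Errors if negative.
#' @export
residual_df <- function(spec, n_categories, n_occasions,
                        n_items = length(n_categories), n_groups = 1L,
                        W = NULL) {
  n_categories <- rep_len(as.integer(n_categories), n_items)
  if (is.null(W)) W <- prod(n_categories)^n_occasions
  P <- count_parameters(spec, n_categories, n_occasions, n_items, n_groups)
  df <- W - P - 1
  if (df < 0)
    stop(sprintf("negative residual df (W = %s, P = %d): model not identified",
                 format(W, scientific = FALSE), P))
  df
}

#' Log-likelihood of the saturated pattern model
#'
#' The saturated reference assigns each distinct observed pattern its
#' empirical proportion.  With missing data the reference is computed
#' within each missingness-pattern stratum (each stratum's observed
#' sub-patterns at their empirical proportions within the stratum), which
#' keeps G-squared nonnegative and comparable across nested fits that
#' marginalize missing cells the same way.
#'
#' @param table a `pattern_table`.
#' @return Saturated log-likelihood.
#' @export
saturated_loglik <- function(table) {
  masks <- pattern_masks(table)
  n_mask <- tapply(table$freq, masks, sum)[masks]
  sum(table$freq * log(table$freq / as.numeric(n_mask)))
}

#' Likelihood-ratio goodness-of-fit statistic
#'
#' `G2 = 2 * (loglik_saturated - loglik_model)`; on complete data this is
#' the familiar `2 * sum(f * log(f / (N * pi_hat)))` over observed
#' patterns.
#'
#' @param loglik converged maximum log-likelihood of the model on `table`.
#' @param table the `pattern_table` the model was fitted to.
#' @return G-squared.  A value below `-1e-6` signals a non-converged or
#'   inconsistent fit and triggers a warning.
#' @export
gsquared <- function(loglik, table) {
  g2 <- 2 * (saturated_loglik(table) - loglik)
  if (g2 < -1e-6)
    warning(sprintf(
      "negative G-squared (%.3g): model log-likelihood exceeds the saturated reference; fit looks inconsistent",
      g2))
  g2
}

#' Information criteria from G-squared
#'
#' `AIC = G2 + 2P`, `BIC = G2 + ln(N) P`, `CAIC = G2 + (ln(N) + 1) P`,
#' `ABIC = G2 + ln((N + 2) / 24) P`.  Two identities follow directly and
#' are useful audits: `AIC - G2 = 2P` and `CAIC - BIC = P`.
#'
#' @param G2 likelihood-ratio statistic.
#' @param P free-parameter count.
#' @param N_effective sample size used in the penalties (respondents
#'   contributing any data to the fit).
#' @return Named numeric vector `AIC`, `BIC`, `CAIC`, `ABIC`.
#' @export
information_criteria <- function(G2, P, N_effective) {
  stopifnot(P >= 0, N_effective > 0)
  c(AIC = G2 + 2 * P,
    BIC = G2 + log(N_effective) * P,
    CAIC = G2 + (log(N_effective) + 1) * P,
    ABIC = G2 + log((N_effective + 2) / 24) * P)
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum(-p * ln p) / (N * ln S)`: 1 means every unit is assigned with
#' certainty, 0 means the posteriors carry no information beyond the
#' prevalences.  Zero posterior entries contribute zero.  Undefined for a
#' single class (the normalizer `ln S` vanishes); an `NA` flagged with an
#' attribute is returned rather than a misleading 0 or 1.
#'
#' @param posteriors N x S matrix of unit-level posterior probabilities.
#' @param weights optional nonnegative unit weights (e.g. pattern
#'   frequencies); default 1.
#' @return Entropy in `[0, 1]`, or flagged `NA` when `S = 1`.
#' @export
relative_entropy <- function(posteriors, weights = NULL) {
  posteriors <- as.matrix(posteriors)
  s <- ncol(posteriors)
  if (is.null(weights)) weights <- rep(1, nrow(posteriors))
  if (s == 1L) {
    out <- NA_real_
    attr(out, "undefined") <- "relative entropy is undefined for S = 1"
    return(out)
  }
  plogp <- posteriors * log(posteriors)
  plogp[posteriors == 0] <- 0
  h <- -sum(weights * rowSums(plogp))
  1 - h / (sum(weights) * log(s))
}

#' Likelihood-ratio difference test for nested fits
#'
#' Compares a restricted model against a freer model fitted to the same
#' data with the same number of statuses: `G2_delta = G2_restricted -
#' G2_free`, `df_delta = P_free - P_restricted`, p-value from the upper
#' tail of the chi-square at `df_delta`.  The chi-square reference is
#' regular only for nested fits with identical S -- never use this test to
#' choose the number of statuses (that is what the information criteria
#' are for).
#'
#' @param restricted,free fit objects (`lca_fit`/`lta_fit`) or lists with
#'   at least `G2` and `P` (and optionally `AIC`, `BIC`) as produced in
#'   `$stats`.
#' @param alpha significance level for the decision (default 0.05).
#' @param arbiter which rule decides when the test and the criteria
#'   disagree: `"lrdt"` (default), `"aic"`, or `"bic"`.  Disagreement is
#'   always recorded in `conflict`.
#' @return An `lta_comparison`: `G2_delta`, `df_delta`, `p_value`,
#'   `delta_AIC`, `delta_BIC` (restricted minus free; negative favors the
#'   restricted model), `decision` (`"restricted_retained"` or
#'   `"free_preferred"`), `conflict`, `rule`.
#' @export
lrdt <- function(restricted, free, alpha = 0.05,
                 arbiter = c("lrdt", "aic", "bic")) {
  arbiter <- match.arg(arbiter)
  sr <- extract_stats(restricted); sf <- extract_stats(free)
  g2_delta <- sr$G2 - sf$G2
  df_delta <- sf$P - sr$P
  if (df_delta < 0)
    stop("models are not nested as given: the free model must have more parameters")
  if (g2_delta < -1e-6)
    stop(sprintf(
      "negative likelihood-ratio difference (%.4g): models are not nested or one fit did not converge",
      g2_delta))
  g2_delta <- max(g2_delta, 0)
  p <- if (df_delta == 0L) 1
       else stats::pchisq(g2_delta, df = df_delta, lower.tail = FALSE)
  delta_aic <- if (!is.null(sr$AIC) && !is.null(sf$AIC)) sr$AIC - sf$AIC
               else g2_delta - 2 * df_delta
  delta_bic <- if (!is.null(sr$BIC) && !is.null(sf$BIC)) sr$BIC - sf$BIC
               else NA_real_
  by_lrdt <- if (p > alpha) "restricted_retained" else "free_preferred"
  by_aic <- if (delta_aic <= 0) "restricted_retained" else "free_preferred"
  by_bic <- if (is.na(delta_bic)) NA_character_
            else if (delta_bic <= 0) "restricted_retained" else "free_preferred"
  decision <- switch(arbiter, lrdt = by_lrdt, aic = by_aic,
                     bic = if (is.na(by_bic)) by_lrdt else by_bic)
  conflict <- length(unique(stats::na.omit(c(by_lrdt, by_aic, by_bic)))) > 1L
  structure(
    list(G2_delta = g2_delta, df_delta = df_delta, p_value = p,
         delta_AIC = delta_aic, delta_BIC = delta_bic,
         decision = decision, conflict = conflict,
         rule = sprintf("%s at alpha = %g", arbiter, alpha),
         alpha = alpha,
         by_criterion = c(lrdt = by_lrdt, aic = by_aic, bic = by_bic)),
    class = "lta_comparison")
}

extract_stats <- function(x) {
  if (inherits(x, c("lca_fit", "lta_fit"))) x$stats
  else if (is.list(x) && !is.null(x$G2)) x
  else stop("expected a fit object or a list with G2 and P")
}

#' @export
print.lta_comparison <- function(x, ...) {
  cat(sprintf("LRDT: G2_delta = %.4g on %d df, p = %.6g\n",
              x$G2_delta, x$df_delta, x$p_value))
  cat(sprintf("  delta AIC = %.4g, delta BIC = %.4g (restricted - free)\n",
              x$delta_AIC, x$delta_BIC))
  cat(sprintf("  decision: %s (%s)%s\n", x$decision, x$rule,
              if (isTRUE(x$conflict)) " [criteria conflict]" else ""))
  invisible(x)
}

# FitStatistics builder shared by the fit functions.  Covariate models
# maximize a likelihood conditional on x, which can legitimately exceed
# the x-marginal saturated reference, so for them G2 is computed without
# the inconsistency warning (differences between nested covariate fits
# remain valid because the same reference cancels).
build_fit_stats <- function(loglik, spec, table, n_effective, entropy,
                            n_occasions, n_groups = 1L) {
  P <- count_parameters(spec, table$item_categories, n_occasions,
                        n_groups = n_groups)
  W <- prod(table$item_categories)^n_occasions
  g2 <- if (length(spec$covariates) > 0L)
    2 * (saturated_loglik(table) - loglik)
  else gsquared(loglik, table)
  ic <- information_criteria(g2, P, n_effective)
  list(loglik = loglik, G2 = g2, P = P, W = W, df = W - P - 1,
       AIC = unname(ic["AIC"]), BIC = unname(ic["BIC"]),
       CAIC = unname(ic["CAIC"]), ABIC = unname(ic["ABIC"]),
       entropy = entropy, N_effective = n_effective)
}
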
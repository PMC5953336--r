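#' Latent transition model specification
#'
#' Collects the structural choices of an LCA/LTA fit: the number of latent
#' statuses, invariance constraints, optional item-response-probability
#' restrictions, covariates, grouping, and estimation settings.
#'
#' @param S number of latent statuses (classes).
#' @param measurement_invariance hold the item-response probabilities
#'   (rho) equal across occasions (the default; statuses then keep the
#'   same meaning over time).
#' @param transition_invariance hold the transition matrix equal across
#'   all adjacent occasion pairs.
#' @param rho_constraints optional list of constraint groups.  Each group
#'   is a list with `cells`, a data frame with columns `status`, `item`
#'   and (when rho varies by occasion) `occasion`, and optionally `fixed`,
#'   a probability vector over the item's categories.  Without `fixed`,
#'   the listed cells' whole category distributions are constrained equal
#'   (estimated by pooling expected counts); with `fixed`, they are held
#'   at the given values.
#' @param covariates character vector of covariate column names entering
#'   the first-occasion prevalence through a multinomial logit.
#' @param covariate_on_transitions also let the covariates act on each
#'   transition-matrix row (per-origin multinomial logits).  Off by
#'   default; guarded by a sparseness check at estimation time.
#' @param group list with logical fields `delta_varies` / `tau_varies`
#'   describing a multiple-group model (rho is always shared across
#'   groups), or `NULL` for a single-group model.
#' @param reference_status reference category for prevalence logits;
#'   `NULL` picks the highest-prevalence status after fitting.
#' @param starts number of random EM starts.
#' @param seed integer seed controlling the full start sequence.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param sparseness_threshold minimum expected status/transition count
#'   tolerated in covariate models before estimation aborts.
#'
#' @return An object of class `lta_spec`.
#' @export
lta_spec <- function(S,
                     measurement_invariance = TRUE,
                     transition_invariance = FALSE,
                     rho_constraints = NULL,
                     covariates = NULL,
                     covariate_on_transitions = FALSE,
                     group = NULL,
                     reference_status = NULL,
                     starts = 50L, seed = NULL,
                     tol = 1e-8, max_iter = 5000L,
                     sparseness_threshold = 1) {
  stopifnot(S >= 1L)
  if (!is.null(rho_constraints)) {
    for (g in rho_constraints) {
      if (is.null(g$cells) || !all(c("status", "item") %in% names(g$cells)))
        stop("each rho constraint group needs a `cells` data frame with ",
             "`status` and `item` columns")
      if (!is.null(g$fixed) &&
          (any(g$fixed < 0) || any(g$fixed > 1) || sum(g$fixed) > 1 + 1e-8))
        stop("fixed rho values must lie in [0,1] and sum to at most 1")
    }
  }
  if (!is.null(group)) {
    group$delta_varies <- isTRUE(group$delta_varies)
    group$tau_varies <- isTRUE(group$tau_varies)
  }
  structure(
    list(S = as.integer(S),
         measurement_invariance = isTRUE(measurement_invariance),
         transition_invariance = isTRUE(transition_invariance),
         rho_constraints = rho_constraints,
         covariates = covariates,
         covariate_on_transitions = isTRUE(covariate_on_transitions),
         group = group,
         reference_status = reference_status,
         starts = as.integer(starts), seed = seed,
         tol = tol, max_iter = as.integer(max_iter),
         sparseness_threshold = sparseness_threshold),
    class = "lta_spec")
}

#' @export
print.lta_spec <- function(x, ...) {
  cat(sprintf("LTA model spec: S = %d statuses\n", x$S))
  cat(sprintf("  measurement invariance: %s; transition invariance: %s\n",
              x$measurement_invariance, x$transition_invariance))
  if (!is.null(x$covariates))
    cat("  prevalence covariates:", paste(x$covariates, collapse = ", "),
        if (x$covariate_on_transitions) "(also on transitions)", "\n")
  if (!is.null(x$rho_constraints))
    cat(sprintf("  %d rho constraint group(s)\n", length(x$rho_constraints)))
  invisible(x)
}
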
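#' One-step latent transition model with prevalence covariates
#'
#' Fits the latent transition model with respondent covariates entering
#' the first-occasion status prevalences through a multinomial logit:
#' respondent i's prior status distribution is the softmax of
#' `beta %*% c(1, x_i)` with the reference status's logit fixed at zero.
#' Estimation is one-step (simultaneous): the E-step uses the
#' respondent-specific prevalences and the M-step refits a weighted
#' multinomial logit (Newton iterations) to the expected status
#' memberships, while the rho and tau M-steps are unchanged unless
#' `covariate_on_transitions` puts per-origin-row logits on the
#' transition matrices as well.  Covariate values are used raw (odds
#' ratios are per unit of the supplied covariate); respondents with
#' missing covariate values are excluded from this model only.
#'
#' Transition covariates are guarded by a sparseness check: if any
#' expected origin-to-destination count falls below
#' `spec$sparseness_threshold`, estimation aborts with an error naming
#' the sparse cells, since the logits for those rows are not estimable.
#'
#' @param panel a [response_panel()] carrying the covariate columns.
#' @param spec an [lta_spec()] with non-empty `covariates`.
#' @param base_fit optional `lta_fit` of the same structural model
#'   without covariates; used as a warm start (slopes at zero), in which
#'   case a single EM run replaces the random multi-start search.
#' @return An `lta_fit` whose `beta` holds the prevalence logit
#'   coefficients ((S-1) x (1 + K): statuses 2..S against status 1, the
#'   highest-prevalence reference) and, when transition covariates are on,
#'   `beta_tau`, a list (per transition matrix, per origin row) of logit
#'   coefficients.
#' @export
fit_lta_covariates <- function(panel, spec, base_fit = NULL) {
  if (length(spec$covariates) == 0L)
    stop("spec carries no covariates; use fit_lta()")
  missing_cols <- setdiff(spec$covariates, names(panel$covariates))
  if (length(missing_cols))
    stop("panel lacks covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  constant <- vapply(spec$covariates, function(v) {
    x <- panel$covariates[[v]]
    stats::var(x[!is.na(x)]) == 0 || all(is.na(x))
  }, logical(1L))
  if (any(constant)) {
    fit <- fit_constant_covariate(panel, spec, names(constant)[constant],
                                  base_fit)
    return(fit)
  }
  prep <- prepare_lta_data(panel, spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (!is.null(base_fit)) {
    runs <- list(em_lta(prep, spec, warm_start_init(base_fit, spec, prep)))
    run <- runs[[1L]]
    if (!run$converged)
      stop(structure(class = c("lta_estimation_error", "error", "condition"),
                     list(message = "warm-started EM did not converge",
                          call = sys.call(), report = run)))
    run$convergence <- list(n_starts = 1L, best_loglik = run$loglik,
                            n_starts_at_best = 1L,
                            iterations = run$iterations, converged = TRUE)
  } else {
    runs <- lapply(seq_len(spec$starts), function(r)
      em_lta(prep, spec, random_lta_init(spec, prep)))
    run <- pick_best_run(runs, spec$starts, spec$S, prep$table, spec$tol)
  }
  finalize_lta_fit(run, spec, prep)
}

# a covariate with no variation cannot carry a slope: drop it to the
# no-covariate model and flag the slopes as undefined
fit_constant_covariate <- function(panel, spec, which_const, base_fit) {
  warning("covariate(s) constant across respondents: ",
          paste(which_const, collapse = ", "),
          "; slopes are undefined and the fit equals the covariate-free model")
  spec0 <- spec
  spec0$covariates <- NULL
  fit <- if (!is.null(base_fit)) base_fit else fit_lta(panel, spec0)
  k <- length(spec$covariates)
  fit$beta <- matrix(NA_real_, spec$S - 1L, 1L + k,
                     dimnames = list(paste0("status", 2:spec$S),
                                     c("(Intercept)", spec$covariates)))
  attr(fit$beta, "undefined") <- which_const
  fit
}

warm_start_init <- function(base_fit, spec, prep) {
  init <- params_as_init(base_fit, prep)
  S <- spec$S; k <- ncol(prep$X) - 1L
  d <- if (is.matrix(base_fit$delta)) colMeans(base_fit$delta)
       else base_fit$delta
  init$beta <- cbind(log(d[-1L] / d[1L]), matrix(0, S - 1L, k))
  colnames(init$beta) <- colnames(prep$X)
  if (spec$covariate_on_transitions) {
    n_mats <- if (spec$transition_invariance) 1L else prep$T_occ - 1L
    init$beta_tau <- lapply(seq_len(n_mats), function(m) {
      tm <- base_fit$tau[[m]]
      if (is.list(tm)) tm <- tm[[1L]]
      lapply(seq_len(S), function(s) {
        p <- clamp_prob(tm[s, ])
        cbind(log(p[-1L] / p[1L]), matrix(0, S - 1L, k))
      })
    })
  }
  init
}

#' Odds ratios from multinomial-logit coefficients
#'
#' Entrywise exponentiation: `exp(beta)` is the multiplicative change in
#' the odds of the row's status against the reference status per unit of
#' the column's covariate (per grade level, say).  The reference status
#' carries implicit zeros and is reported as `"Reference"` when printed.
#'
#' @param coef a coefficient matrix (rows = non-reference statuses,
#'   columns = intercept then covariates), or an `lta_fit` with `beta`.
#' @return Matrix of odds (ratios) the same shape as the coefficients.
#' @export
odds_ratios <- function(coef) {
  if (inherits(coef, "lta_fit")) coef <- coef$beta
  if (is.null(coef) || !is.numeric(coef))
    stop("no logit coefficients in this object")
  exp(coef)
}

#' Test a covariate's effect on status prevalences
#'
#' Likelihood-ratio difference test of the model with covariates against
#' the nested model with all slopes at zero (the covariate-free fit):
#' `G2_delta = 2 * (loglik_with - loglik_without)` on as many degrees of
#' freedom as there are slope parameters.
#'
#' @param fit_with,fit_without fits on the same data: with covariates and
#'   without (or their `$stats`).
#' @param alpha significance level (default 0.05).
#' @return An `lta_comparison` (see [lrdt()]); the covariate effect is
#'   significant when `p_value <= alpha`.
#' @export
covariate_effect_test <- function(fit_with, fit_without, alpha = 0.05) {
  lrdt(restricted = fit_without, free = fit_with, alpha = alpha)
}

# ---- weighted multinomial logit by Newton iterations -------------------
# maximizes sum_i sum_s Y[i,s] * log p[i,s], p = softmax(0, X beta') with
# the first category as reference; Y may hold fractional expected counts.
multinom_logit_irls <- function(X, Y, start = NULL, max_iter = 50L,
                                tol = 1e-10) {
  n <- nrow(X); k <- ncol(X); S <- ncol(Y)
  w <- rowSums(Y)
  beta <- if (is.null(start)) matrix(0, S - 1L, k) else start
  npar <- (S - 1L) * k
  ll_of <- function(beta) {
    eta <- cbind(0, X %*% t(beta))
    eta <- eta - apply(eta, 1L, max)
    sum(Y * eta) - sum(w * log(rowSums(exp(eta))))
  }
  ll <- ll_of(beta)
  for (it in seq_len(max_iter)) {
    eta <- cbind(0, X %*% t(beta))
    p <- exp(eta - apply(eta, 1L, max))
    p <- p / rowSums(p)
    # gradient (statuses 2..S stacked over coefficients)
    resid <- Y[, -1L, drop = FALSE] - w * p[, -1L, drop = FALSE]
    grad <- as.vector(t(X) %*% resid)  # k x (S-1), column-major
    H <- matrix(0, npar, npar)
    for (s1 in seq_len(S - 1L)) for (s2 in seq_len(S - 1L)) {
      v <- w * (p[, s1 + 1L] * ((s1 == s2) - p[, s2 + 1L]))
      blk <- t(X) %*% (X * v)
      r1 <- (s1 - 1L) * k + seq_len(k); r2 <- (s2 - 1L) * k + seq_len(k)
      H[r1, r2] <- blk
    }
    step <- tryCatch(solve(H + diag(1e-10, npar), grad),
                     error = function(e) grad / max(diag(H), 1))
    # step halving keeps the inner loop ascending
    for (half in 0:20) {
      cand <- beta + matrix(step, S - 1L, k, byrow = TRUE) / 2^half
      ll_new <- ll_of(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    beta_new <- cand
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      beta <- beta_new; break
    }
    beta <- beta_new; ll <- ll_new
  }
  colnames(beta) <- colnames(X)
  beta
}
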
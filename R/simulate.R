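#' Generating truths for latent transition panels
#'
#' An `lta_truth` fully specifies a latent transition data-generating
#' process: first-occasion status prevalences `delta`, occasion-specific
#' transition matrices `tau`, status-specific item-response probabilities
#' `rho`, an optional covariate acting on the prevalence logits, and a
#' monotone attrition schedule.
#'
#' @param S number of latent statuses.
#' @param T_occ number of occasions.
#' @param n_categories categories per item (scalar or length-J vector).
#' @param rho item-response probabilities: an `S x J x C` array (shared
#'   across occasions) or a list of T such arrays (occasion-varying).  For
#'   binary items an `S x J` matrix of "category 2" probabilities is
#'   accepted and expanded.
#' @param delta length-S first-occasion prevalence vector (sums to 1).
#' @param tau an `S x S` transition matrix (shared across all adjacent
#'   occasion pairs) or a list of `T-1` such matrices; rows sum to 1.
#' @param N default number of respondents to simulate.
#' @param covariate optional list describing one prevalence covariate:
#'   `name`, `dist` (`"normal"` or `"uniform"`), `pars` (mean/sd or
#'   min/max), and `beta`, an `(S-1) x 2` matrix of (intercept, slope)
#'   logit coefficients for statuses `2..S` against reference status 1.
#'   When present, a respondent's first-status distribution is the softmax
#'   of `beta %*% c(1, x)` (reference logit 0) instead of `delta`.
#' @param attrition length-T vector of cumulative drop-out probabilities:
#'   entry t is the marginal probability that a respondent has dropped out
#'   by occasion t (all items missing from then on).  Must start at 0 and
#'   be non-decreasing: drop-outs never return.
#' @param item_missing sporadic item-level missingness rate applied on top
#'   of attrition (default 0).
#'
#' @return An `lta_truth` list.
#' @export
lta_truth <- function(S, T_occ, n_categories, rho, delta, tau, N = 1000L,
                      covariate = NULL, attrition = rep(0, T_occ),
                      item_missing = 0) {
  if (is.matrix(rho) && !is.list(rho)) rho <- expand_binary_rho(rho)
  if (!is.list(rho)) rho <- list(shared = rho)
  rho_varying <- is.null(names(rho)) || !identical(names(rho), "shared")
  if (rho_varying && length(rho) != T_occ)
    stop("occasion-varying rho needs one array per occasion")
  j <- dim(rho[[1L]])[2L]
  n_categories <- as.integer(rep_len(n_categories, j))
  for (r in rho) check_rho(r, S, j, max(n_categories))
  delta <- as.numeric(delta)
  stopifnot(length(delta) == S, abs(sum(delta) - 1) < 1e-3, all(delta >= 0))
  delta <- delta / sum(delta)  # absorb printed rounding
  if (!is.list(tau)) tau <- rep(list(tau), max(T_occ - 1L, 0L))
  if (T_occ > 1L && length(tau) == 1L) tau <- rep(tau, T_occ - 1L)
  if (length(tau) != max(T_occ - 1L, 0L))
    stop("need one transition matrix per adjacent occasion pair")
  tau <- lapply(tau, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == S, ncol(m) == S, all(m >= 0))
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-6)) m <- m / rs  # renormalize printed rounding
    m
  })
  attrition <- as.numeric(attrition)
  stopifnot(length(attrition) == T_occ, attrition[1L] == 0,
            all(diff(attrition) >= 0), all(attrition < 1))
  if (!is.null(covariate)) {
    stopifnot(is.matrix(covariate$beta),
              nrow(covariate$beta) == S - 1L, ncol(covariate$beta) == 2L)
    if (is.null(covariate$name)) covariate$name <- "x"
  }
  structure(
    list(S = as.integer(S), T_occ = as.integer(T_occ), J = j,
         n_categories = n_categories, rho = rho, rho_varying = rho_varying,
         delta = delta, tau = tau, N = as.integer(N), covariate = covariate,
         attrition = attrition, item_missing = item_missing),
    class = "lta_truth")
}

expand_binary_rho <- function(p2) {
  s <- nrow(p2); j <- ncol(p2)
  arr <- array(NA_real_, dim = c(s, j, 2L))
  arr[, , 1L] <- 1 - p2
  arr[, , 2L] <- p2
  arr
}

check_rho <- function(rho, S, J, Cmax) {
  stopifnot(length(dim(rho)) == 3L, dim(rho)[1L] == S, dim(rho)[2L] == J,
            dim(rho)[3L] <= Cmax)
  sums <- apply(rho, c(1L, 2L), sum, na.rm = TRUE)
  if (any(abs(sums - 1) > 1e-8))
    stop("each rho category slice must sum to 1")
  invisible(TRUE)
}

truth_rho_at <- function(truth, t) {
  if (truth$rho_varying) truth$rho[[t]] else truth$rho[[1L]]
}

#' Simulate a categorical panel from a generating truth
#'
#' Each respondent's first status is drawn from the prevalence vector
#' (covariate-adjusted through the softmax when the truth carries a
#' covariate model), subsequent statuses follow the Markov chain through
#' the transition matrices, and item responses are drawn from the
#' status-specific item-response probabilities.  Monotone attrition then
#' blanks all items from the drop-out wave onward.  The same seed always
#' reproduces the same panel.
#'
#' @param truth an [lta_truth()].
#' @param N number of respondents (default `truth$N`).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return A list with `panel` (a [response_panel()]) and `statuses`
#'   (the true N x T status matrix).
#' @export
simulate_panel <- function(truth, N = truth$N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- truth$S; T_occ <- truth$T_occ; J <- truth$J
  covariates <- NULL
  if (!is.null(truth$covariate)) {
    cv <- truth$covariate
    x <- switch(cv$dist %||% "normal",
                normal  = stats::rnorm(N, cv$pars[1L] %||% 0, cv$pars[2L] %||% 1),
                uniform = stats::runif(N, cv$pars[1L] %||% 0, cv$pars[2L] %||% 1),
                stop("covariate dist must be 'normal' or 'uniform'"))
    # beta is (S-1) x 2; linear predictor per respondent: beta %*% c(1, x_i)
    eta <- cbind(0, t(cv$beta %*% rbind(1, x)))  # N x S, reference first
    pr1 <- exp(eta - apply(eta, 1L, max))
    pr1 <- pr1 / rowSums(pr1)
    covariates <- data.frame(x = x)
    names(covariates) <- cv$name
  } else {
    pr1 <- matrix(truth$delta, nrow = N, ncol = S, byrow = TRUE)
  }
  statuses <- matrix(NA_integer_, N, T_occ)
  statuses[, 1L] <- vapply(seq_len(N), function(i)
    sample.int(S, 1L, prob = pr1[i, ]), integer(1L))
  if (T_occ > 1L) for (t in 2L:T_occ) {
    tr <- truth$tau[[t - 1L]]
    u <- stats::runif(N)
    cum <- tr[statuses[, t - 1L], , drop = FALSE]
    cum <- t(apply(cum, 1L, cumsum))
    statuses[, t] <- 1L + rowSums(u > cum + 1e-15)
    statuses[, t] <- pmin(statuses[, t], S)
  }
  arr <- array(NA_integer_, dim = c(N, T_occ, J))
  for (t in seq_len(T_occ)) {
    rho <- truth_rho_at(truth, t)
    for (j in seq_len(J)) {
      cj <- truth$n_categories[j]
      p <- rho[statuses[, t], j, seq_len(cj), drop = FALSE]
      p <- matrix(p, nrow = N)
      cum <- t(apply(p, 1L, cumsum))
      u <- stats::runif(N)
      arr[, t, j] <- pmin(1L + rowSums(u > cum + 1e-15), cj)
    }
  }
  # monotone attrition: drop-out wave per respondent
  if (any(truth$attrition > 0)) {
    alive <- rep(TRUE, N)
    dropped <- rep(FALSE, N)
    for (t in seq_len(T_occ)[-1L]) {
      a_prev <- truth$attrition[t - 1L]; a_now <- truth$attrition[t]
      cond <- (a_now - a_prev) / (1 - a_prev)
      newdrop <- !dropped & stats::runif(N) < cond
      dropped <- dropped | newdrop
      arr[dropped, t, ] <- NA_integer_
    }
  }
  if (truth$item_missing > 0) {
    hit <- array(stats::runif(length(arr)) < truth$item_missing, dim = dim(arr))
    arr[hit] <- NA_integer_
  }
  panel <- response_panel(arr, truth$n_categories,
                          covariates = covariates)
  list(panel = panel, statuses = statuses)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in generating truth: school-bullying concern panel
#'
#' A realistic generating truth shaped like a three-wave school survey of
#' adolescent bullying concerns: six binary concern indicators (physical,
#' peer-pressure, cultural exclusion, belief exclusion, rumors, verbal),
#' four latent concern statuses ranging from unconcerned to globally
#' concerned, published-scale prevalences and occasion-specific transition
#' matrices, and the attrition profile of such surveys (about 5.6% lost by
#' wave 2 and 15.3% by wave 3).  The three-status variant merges the two
#' moderate-concern statuses (prevalence-weighted), mirroring how the two
#' central profiles coalesce when one fewer status is extracted.
#'
#' @param S 3 or 4 statuses.
#' @param N default sample size for simulation.
#' @param attrition cumulative drop-out by wave; set `rep(0, 3)` for
#'   complete panels.
#' @return An [lta_truth()] with `T = 3`, six binary items.
#' @export
bullying_truth <- function(S = 4L, N = 1180L,
                           attrition = c(0, 0.0559, 0.1534)) {
  stopifnot(S %in% c(3L, 4L))
  items <- c("Physical", "Talking", "Cultural", "Belief", "Spread", "Verbal")
  # "yes" probabilities per status (columns LS1..LS4)
  p_yes <- matrix(c(
    0.0380, 0.3386, 0.7844, 0.2357,
    0.0375, 0.3568, 0.8232, 0.2919,
    0.0035, 0.0715, 0.7326, 0.3276,
    0.0087, 0.1437, 0.9664, 0.6014,
    0.0549, 0.7499, 0.9597, 0.5069,
    0.0156, 0.5932, 0.9890, 0.3083), nrow = 6L, byrow = TRUE)
  delta <- c(0.5691, 0.2395, 0.0804, 0.1109)
  tau12 <- matrix(c(
    0.8252, 0.0925, 0.0208, 0.0615,
    0.2780, 0.5734, 0.0893, 0.0594,
    0.2707, 0.3309, 0.3785, 0.0198,
    0.3432, 0.0000, 0.0739, 0.5829), nrow = 4L, byrow = TRUE)
  tau23 <- matrix(c(
    0.8518, 0.0703, 0.0143, 0.0637,
    0.3666, 0.5473, 0.0861, 0.0000,
    0.2639, 0.0287, 0.4959, 0.2114,
    0.5492, 0.0000, 0.0000, 0.4508), nrow = 4L, byrow = TRUE)
  if (S == 3L) {
    # merge the two moderate statuses (2 and 4), weights by prevalence
    w <- delta[c(2L, 4L)] / sum(delta[c(2L, 4L)])
    p_yes <- cbind(p_yes[, 1L],
                   p_yes[, 2L] * w[1L] + p_yes[, 4L] * w[2L],
                   p_yes[, 3L])
    merge_tau <- function(m) {
      m2 <- cbind(m[, 1L], m[, 2L] + m[, 4L], m[, 3L])
      rbind(m2[1L, ],
            w[1L] * m2[2L, ] + w[2L] * m2[4L, ],
            m2[3L, ])
    }
    tau12 <- merge_tau(tau12); tau23 <- merge_tau(tau23)
    delta <- c(delta[1L], delta[2L] + delta[4L], delta[3L])
  }
  lta_truth(S = S, T_occ = 3L, n_categories = 2L,
            rho = t(p_yes), delta = delta, tau = list(tau12, tau23),
            N = N, attrition = attrition)
}
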
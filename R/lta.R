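#' Fit a latent transition model by maximum likelihood
#'
#' EM estimation of a first-order latent Markov chain over T occasions:
#' first-occasion status prevalences `delta`, occasion-specific (or
#' shared) transition matrices `tau`, and status-specific item-response
#' probabilities `rho`, optionally held invariant across occasions.  The
#' observed-data likelihood of a response pattern,
#' `P(y) = sum over status sequences of delta * prod(tau) * prod(rho)`,
#' is computed by forward-backward recursions over statuses (never by
#' enumerating the S^T sequences), with per-occasion scaling, so missing
#' items and whole missing occasions (attrition) simply contribute no
#' emission term.  Identical observed patterns share one recursion pass
#' weighted by frequency.  Constraints are enforced exactly at every
#' M-step: invariant rho pools expected counts across occasions, an
#' invariant tau pools across transitions, equality-constrained rho cells
#' pool counts across their group, and fixed cells are held at their
#' values.  Statuses in the returned solution are ordered by descending
#' first-occasion prevalence.
#'
#' @param x a [response_panel()] (required for grouped or covariate
#'   models) or a joint `pattern_table`.
#' @param spec an [lta_spec()].
#' @return An `lta_fit`: `rho` (S x J x C array under measurement
#'   invariance, a list of per-occasion arrays otherwise), `delta`
#'   (vector, or group x S matrix), `tau` (list of S x S matrices, one per
#'   adjacent occasion pair), `beta` (prevalence logit coefficients when
#'   covariates are present), `occupancy` (model-implied status marginals
#'   per occasion), `loglik`, `stats`, `convergence`.
#' @export
fit_lta <- function(x, spec) {
  stopifnot(inherits(spec, "lta_spec"))
  prep <- prepare_lta_data(x, spec)
  if (prep$T_occ < 2L)
    stop("latent transition models need T >= 2 occasions; use fit_lca() for one")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  runs <- vector("list", spec$starts)
  for (r in seq_len(spec$starts)) {
    init <- random_lta_init(spec, prep)
    runs[[r]] <- em_lta(prep, spec, init)
  }
  run <- pick_best_run(runs, spec$starts, spec$S, prep$table, spec$tol)
  finalize_lta_fit(run, spec, prep)
}

# ---- data preparation --------------------------------------------------

prepare_lta_data <- function(x, spec) {
  has_cov <- length(spec$covariates) > 0L
  has_grp <- !is.null(spec$group)
  if (inherits(x, "pattern_table")) {
    if (has_cov || has_grp)
      stop("grouped or covariate models need the full response panel")
    table <- x
    panel <- NULL
  } else {
    panel <- x
    table <- pattern_frequencies(panel, "joint")
  }
  t_occ <- table$n_occasions; j <- table$n_items
  keep <- NULL
  if (has_cov) {
    xm <- as.matrix(panel$covariates[, spec$covariates, drop = FALSE])
    keep <- stats::complete.cases(xm)
    if (any(!keep)) {
      message(sprintf(
        "%d respondent(s) with missing covariate values excluded from the covariate model",
        sum(!keep)))
      # restrict the pattern table too, so the saturated reference behind
      # G-squared describes the same respondents the model is fitted to
      panel <- response_panel(
        panel$responses[keep, , , drop = FALSE], panel$n_categories,
        items = panel$items,
        covariates = panel$covariates[keep, , drop = FALSE],
        group = if (!is.null(panel$group)) panel$group[keep],
        ids = panel$ids[keep])
      table <- pattern_frequencies(panel, "joint")
      xm <- xm[keep, , drop = FALSE]
      keep <- rep(TRUE, nrow(xm))
    }
    pat_idx <- table$respondent_pattern
    key <- paste(pat_idx, apply(xm, 1L, paste, collapse = "\r"))
    first <- !duplicated(key)
    row_of <- match(key, key[first])
    rows <- table$patterns[pat_idx[first], , drop = FALSE]
    w <- as.numeric(tabulate(row_of, nbins = sum(first)))
    X <- cbind(1, xm[first, , drop = FALSE])
    colnames(X) <- c("(Intercept)", spec$covariates)
    row_group <- rep(1L, nrow(rows)); n_groups <- 1L
  } else if (has_grp) {
    if (is.null(panel$group)) stop("spec requests groups but the panel has none")
    g <- as.integer(panel$group)
    key <- paste(table$respondent_pattern, g)
    first <- !duplicated(key)
    row_of <- match(key, key[first])
    rows <- table$patterns[table$respondent_pattern[first], , drop = FALSE]
    w <- as.numeric(tabulate(row_of, nbins = sum(first)))
    row_group <- g[first]
    n_groups <- nlevels(panel$group)
    X <- NULL
  } else {
    rows <- table$patterns
    w <- as.numeric(table$freq)
    X <- NULL
    row_group <- rep(1L, nrow(rows)); n_groups <- 1L
  }
  list(table = table, panel = panel, rows = rows, w = w, X = X,
       row_group = row_group, n_groups = n_groups,
       T_occ = t_occ, J = j, cj = table$item_categories[seq_len(j)],
       n_eff = sum(w))
}

col_of <- function(t, j, J) (t - 1L) * J + j

# emission matrices per occasion: list of R x S, missing cells contribute 1
lta_emissions <- function(rho_sets, set_of_t, rows, cj, T_occ, J) {
  S <- dim(rho_sets[[1L]])[1L]
  lapply(seq_len(T_occ), function(t) {
    rho <- rho_sets[[set_of_t[t]]]
    e <- matrix(1, nrow(rows), S)
    for (jj in seq_len(J)) {
      code <- rows[, col_of(t, jj, J)]
      ok <- !is.na(code)
      if (!any(ok)) next
      e[ok, ] <- e[ok, ] * t(matrix(rho[, jj, ], S))[code[ok], , drop = FALSE]
    }
    e
  })
}

# ---- initialization ----------------------------------------------------

random_lta_init <- function(spec, prep) {
  S <- spec$S
  n_sets <- if (spec$measurement_invariance) 1L else prep$T_occ
  rho_sets <- lapply(seq_len(n_sets),
                     function(i) random_lca_init(S, prep$cj)$rho)
  G <- if (!is.null(spec$group)) prep$n_groups else 1L
  delta <- t(vapply(seq_len(max(
    if (!is.null(spec$group) && spec$group$delta_varies) G else 1L, 1L)),
    function(g) { d <- stats::rgamma(S, 1); d / sum(d) }, numeric(S)))
  n_mats <- if (spec$transition_invariance) 1L else prep$T_occ - 1L
  tau_groups <- if (!is.null(spec$group) && spec$group$tau_varies) G else 1L
  tau <- lapply(seq_len(n_mats), function(m)
    lapply(seq_len(tau_groups), function(g) {
      m0 <- matrix(stats::rgamma(S * S, 1), S, S) + diag(S)  # sticky start
      m0 / rowSums(m0)
    }))
  beta <- NULL
  if (!is.null(prep$X)) {
    # intercepts at the logit of the simplex draw, slopes near zero
    b0 <- log(delta[1L, -1L] / delta[1L, 1L])
    beta <- cbind(b0, matrix(stats::rnorm((S - 1L) * (ncol(prep$X) - 1L),
                                          0, 0.1), S - 1L))
    colnames(beta) <- colnames(prep$X)
  }
  list(rho_sets = rho_sets, delta = delta, tau = tau, beta = beta)
}

# ---- EM core -----------------------------------------------------------

em_lta <- function(prep, spec, init) {
  S <- spec$S; T_occ <- prep$T_occ; J <- prep$J; cj <- prep$cj
  rows <- prep$rows; w <- prep$w; X <- prep$X
  R <- nrow(rows)
  set_of_t <- if (spec$measurement_invariance) rep(1L, T_occ)
              else seq_len(T_occ)
  mat_of_t <- if (spec$transition_invariance) rep(1L, T_occ - 1L)
              else seq_len(T_occ - 1L)
  grp_of_row <- prep$row_group
  delta_varies <- !is.null(spec$group) && spec$group$delta_varies
  tau_varies <- !is.null(spec$group) && spec$group$tau_varies
  rho_sets <- init$rho_sets; delta <- init$delta
  tau <- init$tau; beta <- init$beta
  has_cov <- !is.null(X)
  cov_trans <- has_cov && spec$covariate_on_transitions
  beta_tau <- init$beta_tau
  if (cov_trans && is.null(beta_tau)) {
    k <- ncol(X) - 1L
    beta_tau <- lapply(seq_along(tau), function(m)
      lapply(seq_len(S), function(s) {
        p <- clamp_prob(tau[[m]][[1L]][s, ])
        cbind(log(p[-1L] / p[1L]), matrix(0, S - 1L, k))
      }))
  }
  ll_old <- -Inf; ll_trace <- numeric(0); converged <- FALSE
  gamma <- NULL; xi <- NULL
  softmax_rows <- function(eta) {
    p <- exp(eta - apply(eta, 1L, max)); p / rowSums(p)
  }
  for (it in seq_len(spec$max_iter)) {
    emis <- lta_emissions(rho_sets, set_of_t, rows, cj, T_occ, J)
    prior1 <- if (has_cov) softmax_rows(cbind(0, X %*% t(beta)))
              else delta[if (delta_varies) grp_of_row else rep(1L, R),
                         , drop = FALSE]
    # row-specific transition arrays (R x S x S per transition matrix)
    tau_arr <- NULL
    if (cov_trans) {
      tau_arr <- lapply(seq_along(beta_tau), function(m) {
        arr <- array(0, dim = c(R, S, S))
        for (s in seq_len(S))
          arr[, s, ] <- softmax_rows(cbind(0, X %*% t(beta_tau[[m]][[s]])))
        arr
      })
    }
    trans_apply <- function(v, t, transpose = FALSE) {
      # v: R x S; returns v %*% tau_t rowwise (or %*% t(tau_t))
      m <- mat_of_t[t]
      out <- matrix(0, R, S)
      if (cov_trans) {
        a <- tau_arr[[m]]
        for (s2 in seq_len(S)) for (s1 in seq_len(S))
          if (transpose) out[, s1] <- out[, s1] + v[, s2] * a[, s1, s2]
          else out[, s2] <- out[, s2] + v[, s1] * a[, s1, s2]
      } else {
        g <- if (tau_varies) grp_of_row else rep(1L, R)
        for (gg in unique(g)) {
          sel <- g == gg
          tg <- tau[[m]][[gg]]
          out[sel, ] <- v[sel, , drop = FALSE] %*%
            (if (transpose) t(tg) else tg)
        }
      }
      out
    }
    tau_entry <- function(t, s1, s2) {
      m <- mat_of_t[t]
      if (cov_trans) tau_arr[[m]][, s1, s2]
      else {
        g <- if (tau_varies) grp_of_row else rep(1L, R)
        vapply(seq_len(R), function(i) tau[[m]][[g[i]]][s1, s2], numeric(1L))
      }
    }
    # forward with per-occasion scaling
    f <- vector("list", T_occ); cscale <- matrix(0, R, T_occ)
    f1 <- prior1 * emis[[1L]]
    cscale[, 1L] <- rowSums(f1)
    if (any(cscale[, 1L] <= 0))
      stop("numerical underflow in the forward pass")
    f[[1L]] <- f1 / cscale[, 1L]
    for (t in 2L:T_occ) {
      ft <- trans_apply(f[[t - 1L]], t - 1L) * emis[[t]]
      cscale[, t] <- rowSums(ft)
      if (any(cscale[, t] <= 0))
        stop("numerical underflow in the forward pass")
      f[[t]] <- ft / cscale[, t]
    }
    ll <- sum(w * rowSums(log(cscale)))
    ll_trace <- c(ll_trace, ll)
    # backward + expectations
    b <- vector("list", T_occ)
    b[[T_occ]] <- matrix(1, R, S)
    gamma <- vector("list", T_occ)
    gamma[[T_occ]] <- f[[T_occ]]
    xi <- vector("list", T_occ - 1L)
    for (t in (T_occ - 1L):1L) {
      eb <- emis[[t + 1L]] * b[[t + 1L]]
      b[[t]] <- trans_apply(eb, t, transpose = TRUE) / cscale[, t + 1L]
      xit <- array(0, dim = c(R, S, S))
      if (cov_trans || tau_varies) {
        for (s1 in seq_len(S)) for (s2 in seq_len(S))
          xit[, s1, s2] <- f[[t]][, s1] * tau_entry(t, s1, s2) *
            eb[, s2] / cscale[, t + 1L]
      } else {
        tg <- tau[[mat_of_t[t]]][[1L]]
        for (s1 in seq_len(S)) for (s2 in seq_len(S))
          xit[, s1, s2] <- f[[t]][, s1] * tg[s1, s2] *
            eb[, s2] / cscale[, t + 1L]
      }
      g_t <- f[[t]] * b[[t]]
      gamma[[t]] <- g_t / rowSums(g_t)
      xi[[t]] <- xit
    }
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < spec$tol * (abs(ll_old) + 1)) {
      converged <- TRUE; break
    }
    ll_old <- ll
    # ---- M-step ----
    if (has_cov) {
      beta <- multinom_logit_irls(X, gamma[[1L]] * w, start = beta)
    } else {
      for (g in seq_len(nrow(delta))) {
        sel <- if (delta_varies) grp_of_row == g else rep(TRUE, R)
        d <- colSums(w[sel] * gamma[[1L]][sel, , drop = FALSE])
        d <- clamp_prob(d / sum(d))
        delta[g, ] <- d / sum(d)
      }
    }
    if (cov_trans) {
      for (m in seq_along(beta_tau)) for (s in seq_len(S)) {
        Y <- matrix(0, R, S)
        for (t in which(mat_of_t == m))
          Y <- Y + xi[[t]][, s, ] * w
        expected <- colSums(Y)
        sparse <- which(expected < spec$sparseness_threshold)
        if (length(sparse))
          stop(structure(
            class = c("lta_sparseness_error", "lta_estimation_error",
                      "error", "condition"),
            list(message = sprintf(
              "sparse expected transition counts (origin status %d -> %s: %s); transition logits are not estimable",
              s, paste(sparse, collapse = ","),
              paste(sprintf("%.3f", expected[sparse]), collapse = ",")),
              call = sys.call(-1L))))
        beta_tau[[m]][[s]] <-
          multinom_logit_irls(X, Y, start = beta_tau[[m]][[s]])
      }
    } else {
      for (m in seq_along(tau)) for (g in seq_along(tau[[m]])) {
        cnt <- matrix(0, S, S)
        for (t in which(mat_of_t == m)) {
          sel <- if (tau_varies) grp_of_row == g else rep(TRUE, R)
          xw <- xi[[t]][sel, , , drop = FALSE] * w[sel]
          cnt <- cnt + apply(xw, c(2L, 3L), sum)
        }
        rs <- rowSums(cnt); rs[rs == 0] <- 1
        tm <- clamp_prob(cnt / rs)
        tau[[m]][[g]] <- tm / rowSums(tm)
      }
    }
    rho_sets <- mstep_rho(rho_sets, set_of_t, gamma, rows, w, cj, S, J,
                          T_occ, spec)
  }
  if (cov_trans) {
    # report the population-average transition matrices alongside the logits
    for (m in seq_along(beta_tau)) {
      avg <- matrix(0, S, S)
      for (s in seq_len(S)) {
        p <- exp(cbind(0, X %*% t(beta_tau[[m]][[s]])))
        p <- p / rowSums(p)
        avg[s, ] <- colSums(w * p) / sum(w)
      }
      tau[[m]][[1L]] <- avg
    }
  }
  list(rho_sets = rho_sets, delta = delta, tau = tau, beta = beta,
       beta_tau = beta_tau, loglik = ll, iterations = it,
       converged = converged, ll_trace = ll_trace, gamma = gamma, xi = xi,
       posteriors = gamma[[1L]])
}

mstep_rho <- function(rho_sets, set_of_t, gamma, rows, w, cj, S, J, T_occ,
                      spec) {
  cmax <- max(cj)
  counts <- lapply(seq_along(rho_sets),
                   function(i) array(0, dim = c(S, J, cmax)))
  for (t in seq_len(T_occ)) {
    set <- set_of_t[t]
    wz <- gamma[[t]] * w
    for (jj in seq_len(J)) {
      code <- rows[, col_of(t, jj, J)]
      for (cc in seq_len(cj[jj])) {
        sel <- !is.na(code) & code == cc
        if (any(sel))
          counts[[set]][, jj, cc] <- counts[[set]][, jj, cc] +
            colSums(wz[sel, , drop = FALSE])
      }
    }
  }
  # equality groups: pool expected counts across member cells
  if (!is.null(spec$rho_constraints)) {
    for (gc in spec$rho_constraints) {
      cells <- gc$cells
      occ <- if ("occasion" %in% names(cells)) cells$occasion
             else rep(1L, nrow(cells))
      set_idx <- if (length(rho_sets) == 1L) rep(1L, nrow(cells))
                 else set_of_t[occ]
      if (is.null(gc$fixed)) {
        pooled <- 0
        for (i in seq_len(nrow(cells)))
          pooled <- pooled + counts[[set_idx[i]]][cells$status[i],
                                                  cells$item[i], ]
        for (i in seq_len(nrow(cells)))
          counts[[set_idx[i]]][cells$status[i], cells$item[i], ] <- pooled
      }
    }
  }
  for (set in seq_along(rho_sets)) {
    for (jj in seq_len(J)) {
      cidx <- seq_len(cj[jj])
      slice <- counts[[set]][, jj, cidx, drop = FALSE]
      slice <- matrix(slice, S)
      denom <- rowSums(slice); denom[denom == 0] <- 1
      slice <- clamp_prob(slice / denom)
      rho_sets[[set]][, jj, cidx] <- slice / rowSums(slice)
    }
  }
  # fixed-value cells are held exactly
  if (!is.null(spec$rho_constraints)) {
    for (gc in spec$rho_constraints) {
      if (is.null(gc$fixed)) next
      fixed <- gc$fixed
      cells <- gc$cells
      occ <- if ("occasion" %in% names(cells)) cells$occasion
             else rep(1L, nrow(cells))
      set_idx <- if (length(rho_sets) == 1L) rep(1L, nrow(cells))
                 else set_of_t[occ]
      if (abs(sum(fixed) - 1) > 1e-8)
        stop("fixed rho values must form a full category distribution (sum to 1)")
      for (i in seq_len(nrow(cells)))
        rho_sets[[set_idx[i]]][cells$status[i], cells$item[i],
                               seq_along(fixed)] <- fixed
    }
  }
  rho_sets
}

# ---- finalization ------------------------------------------------------

finalize_lta_fit <- function(run, spec, prep) {
  S <- spec$S
  # order statuses by descending first-occasion prevalence
  prev1 <- if (!is.null(run$beta) && !anyNA(run$beta)) {
    eta <- cbind(0, prep$X %*% t(run$beta))
    pr <- exp(eta - apply(eta, 1L, max)); pr <- pr / rowSums(pr)
    colSums(prep$w * pr) / sum(prep$w)
  } else if (nrow(run$delta) > 1L) {
    colMeans(run$delta)
  } else run$delta[1L, ]
  ord <- order(prev1, decreasing = TRUE)
  run$rho_sets <- lapply(run$rho_sets,
                         function(r) r[ord, , , drop = FALSE])
  run$delta <- run$delta[, ord, drop = FALSE]
  run$tau <- lapply(run$tau, function(mats)
    lapply(mats, function(m) m[ord, ord, drop = FALSE]))
  relabel_logits <- function(bmat) {
    # permute the full coefficient matrix (zero row for the old reference)
    # and re-reference against the new first status
    full <- rbind(0, bmat)[ord, , drop = FALSE]
    out <- sweep(full, 2L, full[1L, ])[-1L, , drop = FALSE]
    rownames(out) <- paste0("status", seq_len(S))[-1L]
    out
  }
  if (!is.null(run$beta) && !anyNA(run$beta))
    run$beta <- relabel_logits(run$beta)
  if (!is.null(run$beta_tau))
    run$beta_tau <- lapply(run$beta_tau, function(mats)
      lapply(seq_len(S), function(s) relabel_logits(mats[[ord[s]]])))
  run$gamma <- lapply(run$gamma, function(g) g[, ord, drop = FALSE])
  run$xi <- lapply(run$xi, function(x) x[, ord, ord, drop = FALSE])
  t_occ <- prep$T_occ
  mat_of_t <- if (spec$transition_invariance) rep(1L, t_occ - 1L)
              else seq_len(t_occ - 1L)
  tau_list <- lapply(seq_len(t_occ - 1L), function(t) {
    m <- run$tau[[mat_of_t[t]]]
    if (length(m) == 1L) m[[1L]] else m
  })
  delta_out <- if (!is.null(run$beta)) prev1[ord]
               else if (nrow(run$delta) == 1L) run$delta[1L, ]
               else run$delta
  # model-implied status marginals per occasion (delta, delta tau, ...)
  occupancy <- matrix(NA_real_, t_occ, S,
                      dimnames = list(paste0("t", seq_len(t_occ)),
                                      paste0("status", seq_len(S))))
  occupancy[1L, ] <- if (is.matrix(delta_out)) colMeans(delta_out)
                     else delta_out
  for (t in seq_len(t_occ - 1L)) {
    tl <- tau_list[[t]]
    if (is.list(tl)) tl <- Reduce(`+`, tl) / length(tl)
    occupancy[t + 1L, ] <- occupancy[t, ] %*% tl
  }
  rho_out <- if (spec$measurement_invariance) run$rho_sets[[1L]]
             else run$rho_sets
  nm <- prep$table$items
  if (spec$measurement_invariance)
    dimnames(rho_out) <- list(paste0("status", seq_len(S)), nm, NULL)
  else
    rho_out <- lapply(rho_out, function(r) {
      dimnames(r) <- list(paste0("status", seq_len(S)), nm, NULL); r
    })
  entropy <- relative_entropy(run$gamma[[1L]], weights = prep$w)
  stats <- build_fit_stats(run$loglik, spec, prep$table, prep$n_eff,
                           entropy, n_occasions = t_occ,
                           n_groups = prep$n_groups)
  if (prep$n_eff / stats$P < 5)
    warning(sprintf(
      "only %.1f observations per parameter (N = %d, P = %d); a positive df does not guarantee identification",
      prep$n_eff / stats$P, prep$n_eff, stats$P))
  structure(
    list(rho = rho_out, delta = delta_out, tau = tau_list,
         beta = run$beta, beta_tau = run$beta_tau, occupancy = occupancy,
         loglik = run$loglik, stats = stats,
         convergence = run$convergence, ll_trace = run$ll_trace,
         spec = spec, prep = prep, S = S,
         gamma = run$gamma, xi = run$xi),
    class = "lta_fit")
}

#' @export
print.lta_fit <- function(x, ...) {
  cat(sprintf("Latent transition fit: S = %d statuses over %d occasions, loglik = %.4f\n",
              x$S, x$prep$T_occ, x$loglik))
  cat(sprintf("  G2 = %.2f, P = %d, df = %s, AIC = %.2f, BIC = %.2f\n",
              x$stats$G2, x$stats$P,
              format(x$stats$df, scientific = FALSE),
              x$stats$AIC, x$stats$BIC))
  cat("  status prevalences by occasion (model-implied):\n")
  print(round(x$occupancy, 4))
  invisible(x)
}

#' Smoothed status posteriors
#'
#' Forward-backward smoothing for each row of a pattern table under a
#' fitted latent transition model: per-occasion marginal status
#' probabilities and the pairwise joint probabilities of each adjacent
#' transition.  Per-occasion scaling keeps the recursions away from
#' underflow; marginals sum to 1 and each pairwise joint marginalizes to
#' its adjacent marginals.
#'
#' @param fit an `lta_fit`.
#' @param table optional joint `pattern_table` (defaults to the fitted
#'   data's unit rows).
#' @return List with `marginals` (R x S x T array) and `pairwise` (list of
#'   R x S x S arrays, one per adjacent occasion pair).
#' @export
status_posteriors <- function(fit, table = NULL) {
  if (is.null(table)) {
    gm <- fit$gamma
    marg <- array(0, dim = c(nrow(gm[[1L]]), fit$S, length(gm)))
    for (t in seq_along(gm)) marg[, , t] <- gm[[t]]
    return(list(marginals = marg, pairwise = fit$xi))
  }
  spec <- fit$spec
  prep <- list(table = table, rows = table$patterns,
               w = as.numeric(table$freq), X = NULL,
               row_group = rep(1L, nrow(table$patterns)), n_groups = 1L,
               T_occ = table$n_occasions, J = table$n_items,
               cj = table$item_categories[seq_len(table$n_items)],
               n_eff = table$N)
  init <- params_as_init(fit, prep)
  spec0 <- spec; spec0$max_iter <- 1L
  run <- em_lta(prep, spec0, init)
  marg <- array(0, dim = c(nrow(prep$rows), fit$S, prep$T_occ))
  for (t in seq_len(prep$T_occ)) marg[, , t] <- run$gamma[[t]]
  list(marginals = marg, pairwise = run$xi)
}

params_as_init <- function(fit, prep) {
  spec <- fit$spec
  rho_sets <- if (spec$measurement_invariance) list(fit$rho) else fit$rho
  delta <- if (is.matrix(fit$delta)) fit$delta else matrix(fit$delta, 1L)
  n_mats <- if (spec$transition_invariance) 1L else prep$T_occ - 1L
  tau <- lapply(seq_len(n_mats), function(m) {
    tm <- fit$tau[[m]]
    if (is.list(tm)) tm else list(tm)
  })
  list(rho_sets = rho_sets, delta = delta, tau = tau, beta = fit$beta)
}

#' Align the statuses of two solutions
#'
#' Finds the permutation of the second solution's statuses minimizing the
#' total absolute difference between the two sets of item-response
#' probabilities (the standard remedy for label switching across starts or
#' models).  The assignment problem is solved exactly by searching all S!
#' permutations, which is instant for the status counts these models use.
#'
#' @param a,b `lta_fit`/`lca_fit` objects, or S x J x C rho arrays.
#' @return List with `permutation` (apply to b's statuses to match a) and
#'   `distance` (residual total absolute rho difference).
#' @export
align_statuses <- function(a, b) {
  ra <- extract_rho(a); rb <- extract_rho(b)
  if (!identical(dim(ra), dim(rb)))
    stop("solutions have mismatched dimensions (S, J or C differ)")
  S <- dim(ra)[1L]
  cost <- matrix(0, S, S)
  for (i in seq_len(S)) for (k in seq_len(S))
    cost[i, k] <- sum(abs(ra[i, , ] - rb[k, , ]))
  perms <- all_permutations(S)
  totals <- vapply(seq_len(nrow(perms)), function(r)
    sum(cost[cbind(seq_len(S), perms[r, ])]), numeric(1L))
  best <- which.min(totals)
  list(permutation = perms[best, ], distance = totals[best])
}

extract_rho <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (inherits(x, c("lca_fit", "lta_fit"))) {
    r <- x$rho
    if (is.list(r)) {
      # occasion-varying: stack occasions along the item axis
      return(array(unlist(lapply(r, identity)),
                   dim = c(dim(r[[1L]])[1L],
                           dim(r[[1L]])[2L] * length(r),
                           dim(r[[1L]])[3L])))
    }
    return(r)
  }
  stop("cannot extract item-response probabilities from this object")
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
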
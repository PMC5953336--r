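#' Fit a latent class model by maximum likelihood
#'
#' EM estimation of an S-class model for one occasion's categorical
#' responses: class prevalences `gamma` and class-specific item-response
#' probabilities `rho`.  The search runs from `starts` random
#' initializations (rho drawn as uniform perturbations around equal
#' category probabilities, gamma from a flat simplex draw; the seed fixes
#' the whole start sequence) and keeps the best converged solution.
#' Missing items are marginalized out of each pattern's likelihood.
#' Classes in the returned solution are ordered by descending prevalence.
#'
#' @param x a single-occasion `pattern_table` (from
#'   [pattern_frequencies()] with `scope = "occasion"`) or a
#'   [response_panel()] together with `occasion`.
#' @param S number of latent classes (>= 1).
#' @param occasion which occasion to tabulate when `x` is a panel.
#' @param starts number of random starts (default 100).
#' @param seed integer seed for the start sequence.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @return An `lca_fit`: `rho` (S x J x C array), `gamma`, `loglik`,
#'   `stats` (G2, P, df, AIC/BIC/CAIC/ABIC, entropy), `convergence`
#'   (start-level report), `posteriors` (per pattern), `table`.
#' @export
fit_lca <- function(x, S, occasion = 1L, starts = 100L, seed = NULL,
                    tol = 1e-8, max_iter = 5000L) {
  table <- if (inherits(x, "response_panel"))
    pattern_frequencies(x, "occasion", occasion) else x
  stopifnot(inherits(table, "pattern_table"), table$n_occasions == 1L,
            S >= 1L, nrow(table$patterns) >= 1L)
  if (S > nrow(table$patterns))
    warning(sprintf(
      "S = %d exceeds the %d distinct observed patterns; the model cannot be identified",
      S, nrow(table$patterns)))
  if (!is.null(seed)) set.seed(seed)
  codes <- table$patterns
  freq <- table$freq
  cj <- table$item_categories
  runs <- vector("list", starts)
  for (r in seq_len(starts)) {
    init <- random_lca_init(S, cj)
    runs[[r]] <- em_lca(codes, freq, cj, S, init, tol, max_iter)
  }
  pick_best_run(runs, starts, S, table, tol) |>
    finalize_lca_fit(table)
}

random_lca_init <- function(S, cj) {
  j <- length(cj)
  rho <- array(0, dim = c(S, j, max(cj)))
  for (jj in seq_len(j)) {
    raw <- matrix(stats::runif(S * cj[jj], 0.25, 0.75), S, cj[jj])
    rho[, jj, seq_len(cj[jj])] <- raw / rowSums(raw)
  }
  g <- stats::rgamma(S, 1)
  list(rho = rho, gamma = g / sum(g))
}

# class-conditional pattern likelihoods: P x S, missing items marginalized
class_likelihoods <- function(rho, codes, cj) {
  p <- nrow(codes); s <- dim(rho)[1L]
  lik <- matrix(1, p, s)
  for (jj in seq_len(ncol(codes))) {
    code <- codes[, jj]
    ok <- !is.na(code)
    if (!any(ok)) next
    # rho[, jj, ] is S x C; index rows = observed codes
    lik[ok, ] <- lik[ok, ] * t(matrix(rho[, jj, ], s))[code[ok], , drop = FALSE]
  }
  lik
}

em_lca <- function(codes, freq, cj, S, init, tol, max_iter) {
  rho <- init$rho; gamma <- init$gamma
  n <- sum(freq)
  ll_old <- -Inf; ll_trace <- numeric(0)
  converged <- FALSE
  obs <- !is.na(codes)
  for (it in seq_len(max_iter)) {
    lik <- class_likelihoods(rho, codes, cj)
    joint <- lik * rep(gamma, each = nrow(lik))
    tot <- rowSums(joint)
    if (any(tot <= 0))
      stop("numerical underflow: a pattern has zero total likelihood")
    ll <- sum(freq * log(tot))
    ll_trace <- c(ll_trace, ll)
    z <- joint / tot
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1)) { converged <- TRUE; break }
    ll_old <- ll
    wz <- z * freq
    gamma <- clamp_prob(colSums(wz) / n)
    gamma <- gamma / sum(gamma)
    for (jj in seq_len(ncol(codes))) {
      code <- codes[, jj]; ok <- obs[, jj]
      cnt <- matrix(0, S, cj[jj])
      for (cc in seq_len(cj[jj])) {
        sel <- ok & code == cc
        if (any(sel)) cnt[, cc] <- colSums(wz[sel, , drop = FALSE])
      }
      denom <- rowSums(cnt)
      denom[denom == 0] <- 1
      slice <- clamp_prob(cnt / denom)
      rho[, jj, seq_len(cj[jj])] <- slice / rowSums(slice)
    }
  }
  list(rho = rho, gamma = gamma, loglik = ll, iterations = it,
       converged = converged, ll_trace = ll_trace, posteriors = z)
}

clamp_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

pick_best_run <- function(runs, starts, S, table, tol) {
  lls <- vapply(runs, `[[`, numeric(1L), "loglik")
  conv <- vapply(runs, `[[`, logical(1L), "converged")
  if (!any(conv)) {
    cond <- structure(
      class = c("lta_estimation_error", "error", "condition"),
      list(message = sprintf(
        "no EM start converged in %d iterations across %d starts (best loglik %.6f)",
        runs[[1L]]$iterations, starts, max(lls)),
        call = sys.call(-1L), report = list(lls = lls, converged = conv)))
    stop(cond)
  }
  best <- which.max(ifelse(conv, lls, -Inf))
  n_at_best <- sum(conv & lls >= lls[best] - 1e-4)
  if (starts >= 2L && n_at_best < 2L)
    warning(sprintf(
      "best log-likelihood reached by only %d of %d starts; solution may not be well identified",
      n_at_best, starts))
  report <- list(n_starts = starts, best_loglik = lls[best],
                 n_starts_at_best = n_at_best,
                 iterations = vapply(runs, `[[`, integer(1L), "iterations"),
                 converged = conv[best])
  run <- runs[[best]]
  run$convergence <- report
  run
}

finalize_lca_fit <- function(run, table) {
  S <- length(run$gamma)
  ord <- order(run$gamma, decreasing = TRUE)
  rho <- run$rho[ord, , , drop = FALSE]
  gamma <- run$gamma[ord]
  post <- run$posteriors[, ord, drop = FALSE]
  spec <- lta_spec(S, starts = run$convergence$n_starts)
  n_eff <- table$N
  entropy <- relative_entropy(post, weights = table$freq)
  stats <- build_fit_stats(run$loglik, spec, table, n_eff, entropy,
                           n_occasions = 1L)
  if (n_eff / stats$P < 5)
    warning(sprintf(
      "only %.1f observations per parameter (N = %d, P = %d); a positive df does not guarantee identification",
      n_eff / stats$P, n_eff, stats$P))
  dimnames(rho) <- list(paste0("class", seq_len(S)), table$items, NULL)
  structure(
    list(rho = rho, gamma = gamma, loglik = run$loglik, stats = stats,
         convergence = run$convergence, posteriors = post,
         ll_trace = run$ll_trace, table = table, S = S),
    class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("Latent class fit: S = %d, loglik = %.4f\n", x$S, x$loglik))
  cat(sprintf("  G2 = %.2f, P = %d, df = %s, AIC = %.2f, BIC = %.2f, entropy = %s\n",
              x$stats$G2, x$stats$P,
              format(x$stats$df, scientific = FALSE),
              x$stats$AIC, x$stats$BIC,
              if (is.na(x$stats$entropy)) "undefined"
              else sprintf("%.3f", x$stats$entropy)))
  cat("  class prevalences:", paste(sprintf("%.3f", x$gamma), collapse = ", "),
      "\n")
  invisible(x)
}

#' Posterior class-membership probabilities
#'
#' Bayes rule over classes for each response pattern, with missing items
#' marginalized; accumulation runs in log space so patterns far from every
#' class profile do not underflow.
#'
#' @param fit an `lca_fit`, or a list with `rho` and `gamma`.
#' @param table a single-occasion `pattern_table` (defaults to the table
#'   the model was fitted to).
#' @return P x S matrix of posterior probabilities; rows sum to 1.
#' @export
lca_posteriors <- function(fit, table = fit$table) {
  rho <- fit$rho; gamma <- fit$gamma
  codes <- table$patterns
  s <- length(gamma)
  loglik <- matrix(log(gamma), nrow(codes), s, byrow = TRUE)
  for (jj in seq_len(ncol(codes))) {
    code <- codes[, jj]; ok <- !is.na(code)
    if (!any(ok)) next
    loglik[ok, ] <- loglik[ok, ] +
      log(t(matrix(rho[, jj, ], s))[code[ok], , drop = FALSE])
  }
  m <- apply(loglik, 1L, max)
  if (any(!is.finite(m)))
    stop("numerical underflow: a pattern has zero likelihood under every class")
  post <- exp(loglik - m)
  post / rowSums(post)
}

#' Modal class assignment
#'
#' @param posteriors matrix of posterior probabilities (rows = units).
#' @return Integer class labels (argmax per row; ties broken toward the
#'   lowest class index) with attribute `"tie"`, a logical vector marking
#'   rows whose maximum was not unique.
#' @export
modal_assignment <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  lab <- max.col(posteriors, ties.method = "first")
  rowmax <- posteriors[cbind(seq_len(nrow(posteriors)), lab)]
  tie <- rowSums(abs(posteriors - rowmax) < 1e-12) > 1L
  structure(lab, tie = tie)
}
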